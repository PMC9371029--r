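# Cross-year ensemble consistency filtering of candidate samples -- the
# label-cleaning core of the pipeline. One model is trained per candidate
# year; a training-year candidate is kept only if the models of the *other*
# years agree with its label (leave-one-year-out unanimity), and a
# test-year candidate only if *all* year models agree.

#' Train one model per candidate year
#'
#' Fits `spec` separately to each year's candidate samples; the resulting
#' bank of models is what votes on individual candidates. Each year's fit
#' receives a deterministic sub-seed so the bank is reproducible as a
#' whole. All models share the feature layout and class set of the inputs.
#'
#' @param candidates Sample table covering the training years.
#' @param years Years to train on (default: all years present).
#' @param spec A [model_spec()] (default: the MLP).
#' @return Named list of [train_model()] results, class `year_model_bank`.
#' @export
train_year_models <- function(candidates, years = NULL,
                              spec = model_spec("mlp")) {
  have <- sort(unique(candidates$year))
  years <- as.integer(years %||% have)
  miss <- setdiff(years, have)
  if (length(miss))
    stopf("no candidate samples for year(s): %s", paste(miss, collapse = ", "))
  bank <- stats::setNames(vector("list", length(years)), as.character(years))
  for (i in seq_along(years)) {
    of_year <- candidates[candidates$year == years[i], , drop = FALSE]
    if (length(unique(of_year$label)) < 2L)
      stopf("year %d is degenerate: a single class among its candidates",
            years[i])
    yspec <- spec
    yspec$seed <- spec$seed + i
    bank[[i]] <- train_model(yspec, of_year)
  }
  class(bank) <- "year_model_bank"
  bank
}

#' @export
print.year_model_bank <- function(x, ...) {
  cat(sprintf("<year_model_bank> %d year model(s): %s (%s)\n", length(x),
              paste(names(x), collapse = ", "), x[[1]]$spec$family))
  invisible(x)
}

vote_filter <- function(candidates, voters, mode) {
  x <- sample_features(candidates)
  m <- length(voters)
  agree <- matrix(FALSE, nrow(candidates), m)
  for (j in seq_len(m))
    agree[, j] <- predict(voters[[j]], x) == candidates$label
  k <- rowSums(agree)
  keep <- if (mode == "unanimous") k == m else k > m / 2
  retained <- candidates[keep, , drop = FALSE]
  discarded <- candidates[!keep, , drop = FALSE]
  retained$provenance <- rep("retained", nrow(retained))
  discarded$provenance <- rep("discarded", nrow(discarded))
  discarded$discard_reason <- sprintf("cross-year vote: %d/%d agreed",
                                      k[!keep], m)
  list(retained = retained, discarded = discarded)
}

#' Filter one training year's candidates by cross-year voting
#'
#' Each candidate of year `year` is predicted by every model in the bank
#' *except* that year's own model. In `"unanimous"` mode (the default) the
#' candidate is retained only if every voter predicts its label; in
#' `"majority"` mode a strict majority suffices. Discarded rows record how
#' the vote went. Filtering never alters labels or features -- only
#' membership.
#'
#' @param candidates Sample table; rows of other years are ignored.
#' @param year The candidate year being filtered (its model abstains).
#' @param bank A [train_year_models()] bank containing at least two other
#'   years.
#' @param mode `"unanimous"` or `"majority"`.
#' @return List with `retained` and `discarded` sample tables.
#' @export
filter_training_year <- function(candidates, year, bank,
                                 mode = c("unanimous", "majority")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bank, "year_model_bank"))
  voters <- bank[names(bank) != as.character(year)]
  if (length(voters) < 2L)
    stopf("bank must contain >= 2 years other than %s", year)
  of_year <- candidates[candidates$year == as.integer(year), , drop = FALSE]
  vote_filter(of_year, voters, mode)
}

#' Filter the test year's candidates by the full model bank
#'
#' Identical to [filter_training_year()] except that *every* model in the
#' bank votes (the test year has no model of its own to exclude), which
#' makes the test-year filter at least as strict as the training-year one
#' at equal vote mode.
#'
#' @inheritParams filter_training_year
#' @param test_year Year of the candidates being filtered.
#' @return List with `retained` and `discarded` sample tables.
#' @export
filter_test_year <- function(candidates, bank, test_year = NULL,
                             mode = c("unanimous", "majority")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bank, "year_model_bank"))
  of_year <- if (is.null(test_year)) candidates else
    candidates[candidates$year == as.integer(test_year), , drop = FALSE]
  vote_filter(of_year, bank, mode)
}

#' Removal-percentage report
#'
#' Per year and class, the percentage of candidates removed by filtering:
#' `(count_before - count_after) / count_before * 100`, plus per-year and
#' per-class means. `after` must be a subset of `before`.
#'
#' @param before Candidate sample table.
#' @param after Retained sample table.
#' @return data.frame of class `filter_report` with columns `year`,
#'   `class`, `n_before`, `n_after`, `removal_pct`; per-class means across
#'   years are in `attr(, "class_means")` and per-year means in
#'   `attr(, "year_means")`.
#' @export
removal_report <- function(before, after) {
  key <- function(df) paste(df$row, df$col, df$year)
  if (!all(key(after) %in% key(before)))
    stopf("'after' must be a subset of 'before'")
  years <- sort(unique(before$year))
  classes <- sort(unique(before$label))
  grid <- expand.grid(year = years, class = classes)
  nb <- mapply(function(y, k) sum(before$year == y & before$label == k),
               grid$year, grid$class)
  na_ <- mapply(function(y, k) sum(after$year == y & after$label == k),
                grid$year, grid$class)
  grid$n_before <- nb
  grid$n_after <- na_
  grid$removal_pct <- ifelse(nb > 0, (nb - na_) / nb * 100, NA_real_)
  out <- grid[order(grid$year, grid$class), ]
  rownames(out) <- NULL
  attr(out, "class_means") <- vapply(split(out$removal_pct, out$class),
                                     mean, numeric(1), na.rm = TRUE)
  attr(out, "year_means") <- vapply(split(out$removal_pct, out$year),
                                    mean, numeric(1), na.rm = TRUE)
  class(out) <- c("filter_report", "data.frame")
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> removal percentage by year and class\n")
  print(as.data.frame(x))
  cat("class means:\n")
  print(round(attr(x, "class_means"), 1))
  invisible(x)
}
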