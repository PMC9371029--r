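# Voting logic is unit-tested with deterministic stub models whose
# predictions are encoded in the feature columns themselves: the stub for
# year 2016+k predicts feature column f_{k-1} verbatim, so the 2017 model
# reads f_0, the 2018 model f_1, and so on -- regardless of which models
# end up voting.

stub_bank <- function(years = 2017:2020, class_list = 1:10) {
  bank <- lapply(years, function(y) {
    k <- y - 2016L
    fixed_model(class_list, 4,
                predict_fun = function(xs, cl) match(xs[, k], cl))
  })
  names(bank) <- as.character(years)
  class(bank) <- "year_model_bank"
  bank
}

vote_table <- function(label, v18, v19, v20, v17 = label, year = 2017) {
  n <- length(label)
  df <- data.frame(row = seq_len(n), col = 1L, year = year, label = label,
                   f_0 = as.numeric(v17), f_1 = as.numeric(v18),
                   f_2 = as.numeric(v19), f_3 = as.numeric(v20),
                   provenance = "candidate",
                   discard_reason = NA_character_)
  class(df) <- c("sample_table", "data.frame")
  df
}

test_that("leave-one-year-out unanimity retains iff all other years agree", {
  bank <- stub_bank(2017:2020)
  # sample 1: all three other-year voters agree with the label -> retained
  # sample 2: 2 of 3 agree -> discarded under unanimity
  # sample 3: none agree -> discarded
  cand <- vote_table(label = c(4L, 4L, 4L),
                     v18 = c(4, 4, 7), v19 = c(4, 4, 8), v20 = c(4, 5, 9))
  res <- filter_training_year(cand, 2017, bank, mode = "unanimous")
  expect_equal(res$retained$row, 1L)
  expect_equal(res$discarded$row, c(2L, 3L))
  expect_equal(res$discarded$discard_reason,
               c("cross-year vote: 2/3 agreed", "cross-year vote: 0/3 agreed"))
  expect_equal(res$retained$provenance, "retained")

  # majority mode keeps the 2/3 sample
  maj <- filter_training_year(cand, 2017, bank, mode = "majority")
  expect_equal(maj$retained$row, c(1L, 2L))

  # the filtered year's own model never votes: its column (f_0) disagrees
  # everywhere and must not matter
  cand$f_0 <- 9
  res2 <- filter_training_year(cand, 2017, bank, mode = "unanimous")
  expect_equal(res2$retained$row, 1L)
})

test_that("test-year filtering polls the full bank and is stricter", {
  bank <- stub_bank(2017:2020)
  # sample 1 agrees with the 2018-2020 models but not 2017's: a
  # leave-2017-out training filter keeps it, the all-model test filter
  # (four voters, no exclusion) must not
  cand <- vote_table(label = c(4L, 4L), v18 = c(4, 4), v19 = c(4, 4),
                     v20 = c(4, 4), v17 = c(9, 4), year = 2021)
  res <- filter_test_year(cand, bank, mode = "unanimous")
  expect_equal(res$retained$row, 2L)
  expect_equal(res$discarded$discard_reason, "cross-year vote: 3/4 agreed")
  loo <- cand
  loo$year <- 2017L
  expect_equal(filter_training_year(loo, 2017, bank, "unanimous")$retained$row,
               c(1L, 2L))
})

test_that("unanimous retention is a subset of majority retention", {
  set.seed(61)
  bank <- stub_bank(2017:2020)
  for (i in 1:20) {
    n <- 30
    cand <- vote_table(label = sample(1:10, n, TRUE),
                       v18 = sample(1:10, n, TRUE),
                       v19 = sample(1:10, n, TRUE),
                       v20 = sample(1:10, n, TRUE))
    # bias some rows toward agreement so both sets are non-trivial
    agree <- sample(n, 10)
    cand$f_1[agree] <- cand$f_2[agree] <- cand$label[agree]
    u <- filter_training_year(cand, 2017, bank, mode = "unanimous")
    m <- filter_training_year(cand, 2017, bank, mode = "majority")
    expect_true(all(u$retained$row %in% m$retained$row))
    # filtering only moves rows between retained/discarded: labels and
    # features are untouched
    both <- rbind(u$retained, u$discarded)
    both <- both[order(both$row), ]
    expect_equal(both$label, cand$label)
    expect_equal(both$f_1, cand$f_1)
  }
})

test_that("year-model banks validate their inputs", {
  d <- blob_data(n_per = 30, sep = 6, seed = 62)
  one_year <- cbind(data.frame(row = 1:60, col = 1L, year = 2017L,
                               label = d$y),
                    as.data.frame(d$x))
  other <- one_year
  other$year <- 2018L
  cand <- rbind(one_year, other)  # identical data in both years
  class(cand) <- c("sample_table", "data.frame")

  expect_error(train_year_models(cand, years = 2017:2019,
                                 spec = model_spec("dt")),
               "2019")
  mono <- cand
  mono$label[mono$year == 2018] <- 1L
  expect_error(train_year_models(mono, spec = model_spec("dt")), "2018")

  # deterministic family, identical data in both years: the two year
  # models make identical predictions
  bank <- train_year_models(cand, spec = model_spec("dt"))
  expect_equal(names(bank), c("2017", "2018"))
  x <- sample_features(cand)
  expect_identical(predict(bank[["2017"]], x), predict(bank[["2018"]], x))
})

test_that("removal percentages follow the count formula", {
  mk <- function(n, year, label) {
    df <- data.frame(row = seq_len(n), col = 1L, year = year, label = label,
                     f_0 = 0)
    class(df) <- c("sample_table", "data.frame")
    df
  }
  before <- mk(100, 2017, rep(1:2, 50))
  after <- before[1:80, ]
  rep <- removal_report(before, after)
  # 100 -> 80 overall; per class 1: 50 -> 40
  expect_equal(rep$removal_pct[rep$class == 1], 20)

  # identity: nothing removed
  rep0 <- removal_report(before, before)
  expect_true(all(rep0$removal_pct == 0))

  # random subset vs direct recount
  set.seed(63)
  big <- mk(500, 2018, sample(1:5, 500, TRUE))
  keep <- big[sample(500, 300), ]
  rep2 <- removal_report(big, keep)
  for (k in 1:5) {
    nb <- sum(big$label == k)
    na_ <- sum(keep$label == k)
    expect_equal(rep2$removal_pct[rep2$class == k], (nb - na_) / nb * 100)
  }
  expect_true(all(rep2$removal_pct >= 0 & rep2$removal_pct <= 100))
  expect_error(removal_report(keep, big), "subset")
})
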