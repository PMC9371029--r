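raw_code,new_code,name
1,1,Corn
12,1,Corn
13,1,Corn
5,2,Soybeans
3,3,Rice
83,4,Water
92,4,Water
111,4,Water
112,4,Water
121,5,Developed
122,5,Developed
123,5,Developed
124,5,Developed
63,6,Forest
141,6,Forest
142,6,Forest
143,6,Forest
176,7,Grassland
59,7,Grassland
87,8,Wetlands
190,8,Wetlands
195,8,Wetlands
64,9,Shrubland
152,9,Shrubland
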