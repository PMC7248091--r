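label,nominal_hb,day,value
L1,0.0475,1,0.0302
L1,0.0475,1,0.0346
L1,0.0475,1,0.0373
L1,0.0475,1,0.0617
L1,0.0475,1,0.0818
L1,0.0475,2,0.0615
L1,0.0475,2,0.0274
L1,0.0475,2,0.0358
L1,0.0475,2,0.0182
L1,0.0475,2,0.0336
L2,0.095,1,0.0509
L2,0.095,1,0.0786
L2,0.095,1,0.113
L2,0.095,1,0.1338
L2,0.095,1,0.0895
L2,0.095,2,0.0549
L2,0.095,2,0.1274
L2,0.095,2,0.0976
L2,0.095,2,0.0972
L2,0.095,2,0.1645
L3,0.1188,1,0.157
L3,0.1188,1,0.1261
L3,0.1188,1,0.1272
L3,0.1188,1,0.0797
L3,0.1188,1,0.1571
L3,0.1188,2,0.1659
L3,0.1188,2,0.0786
L3,0.1188,2,0.1281
L3,0.1188,2,0.1264
L3,0.1188,2,0.1402
L4,0.19,1,0.2675
L4,0.19,1,0.239
L4,0.19,1,0.1852
L4,0.19,1,0.2117
L4,0.19,1,0.2186
L4,0.19,2,0.1597
L4,0.19,2,0.2146
L4,0.19,2,0.2122
L4,0.19,2,0.1997
L4,0.19,2,0.1887
L5,0.2375,1,0.2611
L5,0.2375,1,0.2197
L5,0.2375,1,0.2281
L5,0.2375,1,0.255
L5,0.2375,1,0.2362
L5,0.2375,2,0.2634
L5,0.2375,2,0.2652
L5,0.2375,2,0.3361
L5,0.2375,2,0.2621
L5,0.2375,2,0.2636
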