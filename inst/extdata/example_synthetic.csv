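sample_id,time,status,g1,g2,g3,g4,g5,g6,g7,g8
s0001,1.00291,1,-0.1574,0.1668,-1.3535,1.88,0.3055,-0.3635,-0.4439,0.5054
s0002,0.29276,1,-0.4522,-0.4514,0.6415,1.1922,-0.3114,0.5056,0.0618,-0.499
s0003,0.94581,1,-0.1369,-0.0901,-0.3211,0.2699,0.9041,0.2942,-0.4373,1.0767
s0004,0.0855,1,0.232,-0.2901,0.7745,0.704,0.3722,0.802,-0.3205,0.5671
s0005,3.76028,1,-0.2125,-1.8162,-1.8915,-1.8199,0.1175,-0.1848,-0.6623,-0.3689
s0006,3.96519,1,-0.4037,-1.6063,-1.5962,-0.9859,-0.4221,-0.8649,-0.7247,-1.3959
s0007,1.25954,0,0.0939,-1.9086,-1.2049,-0.8579,-0.9945,0.8071,0.1066,-0.2868
s0008,1.05483,0,-1.3049,0.4057,-0.969,-0.6971,-1.0763,-0.0081,0.3417,-1.4541
s0009,0.65635,1,0.5452,-0.7772,-0.8391,0.5242,0.0552,0.3761,0.9537,1.0964
s0010,2.26709,1,-0.9497,-0.1355,0.0496,0.605,0.0241,-0.824,1.5491,-0.7111
s0011,0.06724,0,-1.1918,0.2111,0.794,-0.2622,0.9523,0.2621,-0.1646,-0.4714
s0012,0.14205,0,0.2508,-0.3955,-0.8133,1.8076,-1.124,-0.7466,-2.5212,0.1757
s0013,0.23976,0,-1.1288,1.0057,-0.3119,0.3715,-0.8525,1.7031,-0.5742,-0.4551
s0014,2.21557,0,0.1329,-0.8324,-1.0538,-0.293,0.5242,0.1632,-0.7729,-0.2103
s0015,0.08901,0,-2.0925,-1.024,-0.5618,-1.0255,-1.7312,-2.0627,-1.6426,-0.1153
s0016,0.0465,1,1.9243,-0.0798,1.2078,0.6539,0.5578,2.1108,1.7011,0.2068
s0017,0.13708,1,0.9331,2.1151,-0.9711,-0.5772,0.844,-0.0472,-0.1383,0.1478
s0018,0.01564,1,-0.2176,0.6945,1.3583,0.5402,-0.395,-1.2082,-0.555,1.3751
s0019,0.13881,0,0.228,-0.728,-1.419,0.3534,-1.0469,-1.315,-0.0286,-0.7273
s0020,0.28021,1,0.7346,1.0347,-0.5024,0.6981,0.1628,0.4126,0.9641,-0.0855
s0021,0.85455,0,-1.1588,-1.1468,-1.4115,0.1309,-0.5081,-0.5415,-0.3834,0.0355
s0022,0.04487,0,-0.2627,1.1723,-1.0887,0.0413,-0.6647,0.2935,0.2549,0.4228
s0023,2.06272,1,-1.5411,-1.7292,-1.0536,-0.053,-0.0297,-0.9543,-0.3457,-1.3082
s0024,0.12706,1,1.1789,-0.4997,1.2487,-0.2709,0.4004,-0.7508,1.1105,0.6872
s0025,2.28899,1,-0.5131,-0.0198,-0.5685,0.9955,0.0836,-0.216,-0.451,-0.077
s0026,0.02864,1,0.8515,1.7556,0.8786,0.2845,1.1597,2.5236,1.6632,0.238
s0027,0.12228,0,-0.0863,0.9388,0.7127,1.2284,-0.6071,0.5777,-0.9497,0.964
s0028,0.0575,0,-0.7721,-0.6043,1.0115,0.681,0.3216,-0.4608,0.5456,1.4472
s0029,0.00617,1,0.4655,1.3372,2.2684,0.5519,1.6098,0.2526,0.6912,1.0946
s0030,0.13772,1,0.1093,2.9652,0.0509,-0.3599,0.9337,2.3282,2.6616,0.3345
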