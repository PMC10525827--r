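scorer,embryokin,embryokin,embryokin,embryokin,embryokin,embryokin,embryokin,embryokin,embryokin,embryokin,embryokin,embryokin
bodyparts,beak_upper,beak_upper,beak_upper,beak_lower,beak_lower,beak_lower,beak_fulcrum,beak_fulcrum,beak_fulcrum,egg_reference,egg_reference,egg_reference
coords,x,y,likelihood,x,y,likelihood,x,y,likelihood,x,y,likelihood
0,100.086,100.015,0.89100000000000001,100.44,109.39,0.98199999999999998,88.052999999999997,105.238,0.84499999999999997,39.935000000000002,40.213999999999999,0.94099999999999995
1,100.19199999999999,100.11499999999999,0.95799999999999996,100.301,109.8,0.97599999999999998,87.328000000000003,105.152,0.92400000000000004,39.954000000000001,40.649000000000001,0.84399999999999997
2,100.035,99.558000000000007,0.84299999999999997,99.975999999999999,109.515,0.84699999999999998,87.888999999999996,104.622,0.80500000000000005,39.822000000000003,40.121000000000002,0.97599999999999998
3,100.178,100.357,0.96199999999999997,99.861999999999995,109.748,0.88200000000000001,87.379000000000005,104.33499999999999,0.872,40.103000000000002,40.304000000000002,0.92300000000000004
4,99.855000000000004,100.473,0.40999999999999998,100.089,109.42100000000001,0.94499999999999995,87.447999999999993,105.012,0.86599999999999999,39.560000000000002,39.783999999999999,0.80900000000000005
5,100.04900000000001,100.14,0.84799999999999998,100.221,109.93300000000001,0.85899999999999999,87.456999999999994,105.318,0.995,39.465000000000003,39.725000000000001,0.95899999999999996
6,99.653999999999996,100.02500000000001,0.879,100.273,110.636,0.94699999999999995,87.632000000000005,105.02500000000001,0.84199999999999997,40.082000000000001,39.898000000000003,0.82799999999999996
7,100.196,100.55800000000001,0.83199999999999996,99.781999999999996,109.908,0.90900000000000003,87.653000000000006,105.56399999999999,0.88800000000000001,40.014000000000003,40.119999999999997,0.92100000000000004
8,99.853999999999999,99.995000000000005,0.81000000000000005,99.453000000000003,109.771,0.84099999999999997,88.662999999999997,105.601,0.82199999999999995,39.823999999999998,39.743000000000002,0.83599999999999997
9,99.481999999999999,100.271,0.82199999999999995,100.56,110.22499999999999,0.98999999999999999,87.938000000000002,104.502,0.84099999999999997,40.159999999999997,40.594999999999999,0.96199999999999997
10,99.701999999999998,99.977999999999994,0.83099999999999996,100.54900000000001,109.902,0.95299999999999996,87.369,105.163,0.81000000000000005,40.234000000000002,39.325000000000003,0.82799999999999996
11,100.369,100.054,0.91100000000000003,100.18000000000001,110.815,0.93000000000000005,88.25,104.913,0.97299999999999998,40.192999999999998,39.777999999999999,0.94499999999999995
12,100.3,100.746,0.94499999999999995,99.941000000000003,109.90000000000001,0.82999999999999996,88.132000000000005,105.33,0.86199999999999999,39.677999999999997,40.543999999999997,0.94699999999999995
13,98.997,100.459,0.97199999999999998,100.051,108.801,0.93500000000000005,87.840999999999994,105.369,0.94299999999999995,40.121000000000002,40.491999999999997,0.873
14,98.784000000000006,99.623999999999995,0.93300000000000005,99.081999999999994,109.52200000000001,0.99299999999999999,87.566999999999993,104.827,0.99399999999999999,39.670000000000002,40.222000000000001,0.80400000000000005
15,100,99.974999999999994,0.83799999999999997,99.453000000000003,110.387,0.83099999999999996,87.968999999999994,105.02800000000001,0.97399999999999998,40.057000000000002,39.703000000000003,0.93200000000000005
16,99.841999999999999,99.849999999999994,0.96399999999999997,99.921000000000006,109.52500000000001,0.94699999999999995,87.790000000000006,105.378,0.88300000000000001,40.295999999999999,40.030000000000001,0.91600000000000004
17,99.302000000000007,100.084,0.81699999999999995,100.027,109.66,0.94599999999999995,88.156999999999996,105.16500000000001,0.82199999999999995,40.554000000000002,40.203000000000003,0.997
18,100.199,100.282,0.82399999999999995,100.036,109.836,0.94699999999999995,87.727999999999994,104.262,0.97199999999999998,39.747,40.837000000000003,0.85599999999999998
19,100.108,100.261,0.96499999999999997,100.129,109.26900000000001,0.95099999999999996,87.700999999999993,105.044,0.84099999999999997,40.094999999999999,40.390999999999998,0.93300000000000005
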