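inoculum_pct,ph,volume_ml,temperature_c,seed_age_days,fermentation_time_days,rotation_speed_rpm,yield
5,1,100,28,8,8,140,45.929
5,2,100,28,8,8,140,35.077
5,3,100,28,8,8,140,45.654
5,4,100,28,8,8,140,534.39
5,5,100,28,8,8,140,702.81
5,6,100,28,8,8,140,1467.7
5,7,100,28,8,8,140,189.20
5,8,100,28,8,8,140,91.049
5,9,100,28,8,8,140,60.841
5,10,100,28,8,8,140,57.255
5,11,100,28,8,8,140,43.238
5,12,100,28,8,8,140,36.288
5,13,100,28,8,8,140,20.943
5,14,100,28,8,8,140,22.306
10,6,40,28,8,8,140,508.495
10,6,60,28,8,8,140,900.662
10,6,80,28,8,8,140,1273.594
10,6,100,28,8,8,140,1153.937
10,6,120,28,8,8,140,1123.330
10,6,140,28,8,8,140,1088.064
2,6,100,28,8,8,140,546.609
4,6,100,28,8,8,140,606.345
6,6,100,28,8,8,140,1320.794
8,6,100,28,8,8,140,1447.519
10,6,100,28,8,8,140,1841.729
12,6,100,28,8,8,140,1631.990
14,6,100,28,8,8,140,481.1172
16,6,100,28,8,8,140,449.5187
10,6,40,25,8,8,140,1145.669
10,6,60,30,8,8,140,1506.055
10,6,80,35,8,8,140,1374.982
10,6,100,40,8,8,140,875.341
2,6,100,28,8,1,150,56.606
4,6,100,28,8,2,150,83.435
6,6,100,28,8,3,150,303.984
8,6,100,28,8,4,150,449.919
10,6,100,28,8,5,150,777.331
12,6,100,28,8,6,150,1103.987
14,6,100,28,8,7,150,1619.554
16,6,100,28,8,8,150,1597.995
10,6,100,28,8,9,150,1546.336
10,6,100,28,8,10,150,1502.487
10,6,100,28,8,11,150,1489.364
10,6,100,28,8,12,150,1465.664
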