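# synthetic calibration curve (identity + sinusoid, constant sigma); not a measured atmospheric curve
# CAL BP, 14C age BP, Sigma
16500.0,16480.0,10.0
16400.0,16382.7,10.0
16300.0,16290.0,10.0
16200.0,16200.0,10.0
16100.0,16110.0,10.0
16000.0,16017.3,10.0
15900.0,15920.0,10.0
15800.0,15817.3,10.0
15700.0,15710.0,10.0
15600.0,15600.0,10.0
15500.0,15490.0,10.0
15400.0,15382.7,10.0
15300.0,15280.0,10.0
15200.0,15182.7,10.0
15100.0,15090.0,10.0
15000.0,15000.0,10.0
14900.0,14910.0,10.0
14800.0,14817.3,10.0
14700.0,14720.0,10.0
14600.0,14617.3,10.0
14500.0,14510.0,10.0
14400.0,14400.0,10.0
14300.0,14290.0,10.0
14200.0,14182.7,10.0
14100.0,14080.0,10.0
14000.0,13982.7,10.0
13900.0,13890.0,10.0
13800.0,13800.0,10.0
13700.0,13710.0,10.0
13600.0,13617.3,10.0
13500.0,13520.0,10.0
13400.0,13417.3,10.0
13300.0,13310.0,10.0
13200.0,13200.0,10.0
13100.0,13090.0,10.0
13000.0,12982.7,10.0
12900.0,12880.0,10.0
12800.0,12782.7,10.0
12700.0,12690.0,10.0
12600.0,12600.0,10.0
12500.0,12510.0,10.0
12400.0,12417.3,10.0
12300.0,12320.0,10.0
12200.0,12217.3,10.0
12100.0,12110.0,10.0
12000.0,12000.0,10.0
11900.0,11890.0,10.0
11800.0,11782.7,10.0
11700.0,11680.0,10.0
11600.0,11582.7,10.0
11500.0,11490.0,10.0
11400.0,11400.0,10.0
11300.0,11310.0,10.0
11200.0,11217.3,10.0
11100.0,11120.0,10.0
11000.0,11017.3,10.0
10900.0,10910.0,10.0
10800.0,10800.0,10.0
10700.0,10690.0,10.0
10600.0,10582.7,10.0
10500.0,10480.0,10.0
10400.0,10382.7,10.0
10300.0,10290.0,10.0
10200.0,10200.0,10.0
10100.0,10110.0,10.0
10000.0,10017.3,10.0
9900.0,9920.0,10.0
9800.0,9817.3,10.0
9700.0,9710.0,10.0
9600.0,9600.0,10.0
9500.0,9490.0,10.0
9400.0,9382.7,10.0
9300.0,9280.0,10.0
9200.0,9182.7,10.0
9100.0,9090.0,10.0
9000.0,9000.0,10.0
8900.0,8910.0,10.0
8800.0,8817.3,10.0
8700.0,8720.0,10.0
8600.0,8617.3,10.0
8500.0,8510.0,10.0
8400.0,8400.0,10.0
8300.0,8290.0,10.0
8200.0,8182.7,10.0
8100.0,8080.0,10.0
8000.0,7982.7,10.0
7900.0,7890.0,10.0
7800.0,7800.0,10.0
7700.0,7710.0,10.0
7600.0,7617.3,10.0
7500.0,7520.0,10.0
7400.0,7417.3,10.0
7300.0,7310.0,10.0
7200.0,7200.0,10.0
7100.0,7090.0,10.0
7000.0,6982.7,10.0
6900.0,6880.0,10.0
6800.0,6782.7,10.0
6700.0,6690.0,10.0
6600.0,6600.0,10.0
6500.0,6510.0,10.0
6400.0,6417.3,10.0
6300.0,6320.0,10.0
6200.0,6217.3,10.0
6100.0,6110.0,10.0
6000.0,6000.0,10.0
5900.0,5890.0,10.0
5800.0,5782.7,10.0
5700.0,5680.0,10.0
5600.0,5582.7,10.0
5500.0,5490.0,10.0
5400.0,5400.0,10.0
5300.0,5310.0,10.0
5200.0,5217.3,10.0
5100.0,5120.0,10.0
5000.0,5017.3,10.0
4900.0,4910.0,10.0
4800.0,4800.0,10.0
4700.0,4690.0,10.0
4600.0,4582.7,10.0
4500.0,4480.0,10.0
4400.0,4382.7,10.0
4300.0,4290.0,10.0
4200.0,4200.0,10.0
4100.0,4110.0,10.0
4000.0,4017.3,10.0
3900.0,3920.0,10.0
3800.0,3817.3,10.0
3700.0,3710.0,10.0
3600.0,3600.0,10.0
3500.0,3490.0,10.0
3400.0,3382.7,10.0
3300.0,3280.0,10.0
3200.0,3182.7,10.0
3100.0,3090.0,10.0
3000.0,3000.0,10.0
2900.0,2910.0,10.0
2800.0,2817.3,10.0
2700.0,2720.0,10.0
2600.0,2617.3,10.0
2500.0,2510.0,10.0
2400.0,2400.0,10.0
2300.0,2290.0,10.0
2200.0,2182.7,10.0
2100.0,2080.0,10.0
2000.0,1982.7,10.0
1900.0,1890.0,10.0
1800.0,1800.0,10.0
1700.0,1710.0,10.0
1600.0,1617.3,10.0
1500.0,1520.0,10.0
1400.0,1417.3,10.0
1300.0,1310.0,10.0
1200.0,1200.0,10.0
1100.0,1090.0,10.0
1000.0,982.7,10.0
900.0,880.0,10.0
800.0,782.7,10.0
700.0,690.0,10.0
600.0,600.0,10.0
500.0,510.0,10.0
400.0,417.3,10.0
300.0,320.0,10.0
200.0,217.3,10.0
100.0,110.0,10.0
0.0,0.0,10.0
-100.0,-110.0,10.0
-200.0,-217.3,10.0
-300.0,-320.0,10.0
-400.0,-417.3,10.0
-500.0,-510.0,10.0
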