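"wavelength_nm","melanin","hb_oxy","hb_deoxy","water","cco"
450,993.73,336.43,553.21,0.00092,0.08
460,920.56,270.05,401.74,0.00071454,0.067719
470,854.18,216.77,291.75,0.00055496,0.057323
480,793.83,174,211.87,0.00043102,0.048522
490,738.87,139.67,153.86,0.00033476,0.041073
500,688.71,112.11,111.73,0.00026,0.034768
510,642.84,129.48,134.85,0.00029015,0.02943
520,600.84,149.54,162.74,0.00032379,0.024912
530,562.3,172.71,196.4,0.00036134,0.021088
540,526.89,199.48,237.03,0.00040324,0.01785
550,494.3,230.39,286.06,0.00045,0.01511
560,464.25,137.01,220.93,0.00062361,0.01279
570,436.52,81.482,170.63,0.00086421,0.010827
580,410.88,48.458,131.78,0.0011976,0.0091653
590,387.15,28.819,101.78,0.0016597,0.0077608
600,365.16,17.139,78.607,0.0023,0.006581
610,344.75,11.12,59.833,0.002457,0.0056168
620,325.78,7.2153,45.543,0.0026248,0.0049112
630,308.14,4.6816,34.666,0.002804,0.0046092
640,291.7,3.0376,26.386,0.0029955,0.0050014
650,276.38,1.9709,20.084,0.0032,0.0064774
660,262.08,1.7496,17.339,0.0036287,0.0092949
670,248.72,1.5532,14.97,0.0041148,0.013202
680,236.22,1.5532,12.913,0.0046661,0.01721
690,224.52,1.5532,11.139,0.0052912,0.019902
700,213.55,1.5532,9.6083,0.006,0.020246
710,203.27,1.7443,9.1499,0.0080448,0.01833
720,193.61,1.9588,8.7134,0.010786,0.015363
730,184.54,2.1998,8.2977,0.014463,0.012921
740,176,2.4704,7.9019,0.019391,0.012115
750,167.97,2.7743,7.5249,0.026,0.013261
760,160.4,3.0383,6.6582,0.024671,0.016082
770,153.27,3.3274,5.8913,0.02341,0.020056
780,146.54,3.6439,5.2128,0.022213,0.024644
790,140.19,3.9906,4.6124,0.021077,0.029336
800,134.18,4.3703,4.0811,0.02,0.033648
810,128.51,4.6034,4.0021,0.023309,0.037123
820,123.13,4.8488,3.9245,0.027165,0.039376
830,118.05,5.1073,3.8485,0.031659,0.040142
840,113.23,5.3796,3.774,0.036896,0.039328
850,108.66,5.6665,3.7009,0.043,0.037026
860,104.33,5.8091,3.773,0.047128,0.033497
870,100.21,5.9552,3.8465,0.051652,0.029119
880,96.305,6.1051,3.9215,0.05661,0.024323
890,92.592,6.2588,3.9979,0.062044,0.019522
900,89.06,6.4163,4.0758,0.068,0.015057
910,85.701,6.364,4.0082,0.08892,0.011159
920,82.503,6.3122,3.9418,0.11628,0.0079477
930,79.456,6.2608,3.8765,0.15205,0.0054402
940,76.553,6.2098,3.8122,0.19883,0.0035796
950,73.785,6.1592,3.7491,0.26,0.0022646
960,71.145,6.1047,3.6939,0.34205,0.0013782
970,68.625,6.0506,3.6396,0.45,0.00080742
980,66.219,5.9971,3.586,0.41774,0.00045602
990,63.92,5.944,3.5333,0.3878,0.00024891
1000,61.723,5.8914,3.4813,0.36,0.00013191
1010,59.623,5.8368,3.391,0.29804,6.8427e-05
1020,57.613,5.7828,3.3031,0.24674,3.526e-05
1030,55.69,5.7292,3.2175,0.20427,1.8487e-05
1040,53.848,5.6762,3.1341,0.16911,1.0201e-05
1050,52.085,5.6236,3.0528,0.14,6.1329e-06
1060,50.395,5.569,2.9739,0.14554,4.0912e-06
1070,48.775,5.5149,2.8969,0.15131,2.9996e-06
1080,47.221,5.4614,2.822,0.1573,2.352e-06
1090,45.73,5.4083,2.749,0.16353,1.9185e-06
1100,44.3,5.3558,2.6779,0.17,1.5971e-06
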