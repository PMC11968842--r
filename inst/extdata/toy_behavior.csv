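animal_id,time_s,speed_mm_s,curvature_deriv_rad_s,pumping_hz
w1,0,0.0221,0.0861,3
w1,0.5,0.0364,-0.1336,5
w1,1,0.0368,-0.1153,5
w1,1.5,0.0167,-0.2283,3
w1,2,0.0224,0.197,4
w1,2.5,0.0408,-0.4676,1
w1,3,0.0209,-0.1265,7
w1,3.5,0.0477,0.3693,2
w1,4,0.019,-0.2528,8
w1,4.5,0.0427,0.425,4
w1,5,0.0224,-0.0965,5
w1,5.5,0.0161,-0.4202,4
w1,6,0.0211,0.5493,5
w1,6.5,0.0191,0.1601,5
w1,7,0.0262,-0.6077,4
w1,7.5,0.03,0.1872,3
w1,8,0.076,-0.3482,5
w1,8.5,0.0135,0.1969,5
w1,9,0.0418,0.1049,8
w1,9.5,0.0254,0.2209,3
w1,10,0.044,-0.2331,5
w1,10.5,0.0669,0.4877,3
w1,11,0.0739,-0.0966,4
w1,11.5,0.0399,0.1782,4
w1,12,0.0101,-0.0048,4
w1,12.5,0.0342,-0.0495,4
w1,13,0.0179,-0.3709,7
w1,13.5,0.047,0.9859,6
w1,14,0.0295,0.1059,6
w1,14.5,8e-4,0.056,0
w1,15,0.0039,-0.0732,0
w1,15.5,0.0029,-0.0647,0
w1,16,0.0034,0.0369,0
w1,16.5,0.0024,0.0106,0
w1,17,0.0012,0.0426,0
w1,17.5,0.0072,0.0175,0
w1,18,0.0018,-0.0027,0
w1,18.5,0.0077,-0.048,0
w1,19,0.0011,0.0137,0
w1,19.5,5e-4,0.0782,0
w1,20,0.0032,0.0739,0
w1,20.5,0.0044,-0.0739,0
w1,21,0.007,0.014,0
w1,21.5,0.0018,0.0201,0
w1,22,0.0074,0.0324,0
w1,22.5,0.002,-0.0167,0
w1,23,0.0066,0.0776,0
w1,23.5,0.0049,0.0612,0
w1,24,0.0035,-0.0797,0
w1,24.5,0.0012,-0.0648,0
w1,25,0.0047,-0.0544,0
w1,25.5,3e-4,-0.0025,0
w1,26,0.0026,0.0606,0
w1,26.5,0.002,0.0473,0
w1,27,0.0024,-0.0295,0
w1,27.5,0.0038,-0.0643,0
w1,28,0.0021,-0.0724,0
w1,28.5,0.0065,-0.0724,0
w1,29,0.0038,0.0595,0
w1,29.5,0.0048,0.0194,0
w1,30,0.0019,-0.0199,0
w1,30.5,0.0039,-0.0585,0
w1,31,0.0049,0.0112,0
w1,31.5,0.0024,0.0247,0
w1,32,0.0053,-0.0375,0
w1,32.5,6e-4,0.0792,0
w1,33,0.0033,-0.0719,0
w1,33.5,3e-4,-0.0679,0
w1,34,0.1624,0.2086,4
w1,34.5,0.0352,0.3592,3
w1,35,0.0713,0.0301,6
w1,35.5,0.0334,-0.2724,3
w1,36,0.0695,0.3615,5
w1,36.5,0.0714,0.04,7
w1,37,0.0271,-0.0475,5
w1,37.5,0.0214,0.5793,6
w1,38,0.0488,0.1286,3
w1,38.5,0.0372,0.1665,3
w1,39,0.0273,-0.2896,5
w1,39.5,0.0813,-0.327,5
w1,40,0.1159,0.5699,6
w1,40.5,0.0544,-0.1286,3
w1,41,0.0132,-0.0227,6
w1,41.5,0.0999,0.1667,5
w1,42,0.0678,0.0228,3
w1,42.5,0.0022,-0.0398,0
w1,43,0.0035,-0.0783,0
w1,43.5,0.005,-0.0483,0
w1,44,0.0062,0.0486,0
w1,44.5,0.0039,0.0078,0
w1,45,0.0014,0.0179,0
w1,45.5,0.0055,-0.0372,0
w1,46,0.0063,-0.0591,0
w1,46.5,0.0022,-0.0731,0
w1,47,0.0075,0.0535,0
w1,47.5,0.0013,0.0421,0
w1,48,0.0011,0.0234,0
w1,48.5,0.0013,-0.0512,0
w1,49,0.0024,-0.003,0
w1,49.5,0.0033,0.0793,0
w1,50,6e-4,0.0578,0
w1,50.5,0.0071,-0.0313,0
w1,51,9e-4,0.0056,0
w1,51.5,6e-4,-0.0491,0
w1,52,0.0047,-0.0334,0
w1,52.5,0.0256,-0.2154,3
w1,53,0.0472,0.0456,4
w1,53.5,0.1133,0.3684,5
w1,54,0.0444,-0.2684,3
w1,54.5,0.0479,-0.0112,4
w1,55,0.0364,-0.49,6
w1,55.5,0.0758,-0.1439,3
w1,56,0.0185,-0.0213,3
w1,56.5,0.0138,-0.0383,3
w1,57,0.0423,-0.555,5
w1,57.5,0.0536,0.0428,3
w1,58,0.0126,-0.1046,5
w1,58.5,0.0384,-0.321,7
w1,59,0.0998,-0.1637,5
w1,59.5,0.1489,0.7416,4
w2,0,0.0469,0.5665,5
w2,0.5,0.0632,0.1775,4
w2,1,0.0686,0.0909,2
w2,1.5,0.0213,-0.0866,5
w2,2,0.0708,0.3709,4
w2,2.5,0.1672,-0.4405,4
w2,3,0.0314,-0.1513,5
w2,3.5,0.0307,0.2512,5
w2,4,0.0317,0.4485,4
w2,4.5,0.0155,0.1832,3
w2,5,0.015,-0.3708,4
w2,5.5,0.0436,0.0587,6
w2,6,0.0123,-0.206,5
w2,6.5,0.0187,-0.1657,7
w2,7,0.0252,0.1677,4
w2,7.5,0.0367,-0.2213,4
w2,8,0.0557,0.2311,3
w2,8.5,0.0364,-0.2863,4
w2,9,0.0202,-0.4022,4
w2,9.5,0.053,0.1678,7
w2,10,0.037,0.0274,4
w2,10.5,0.0458,-0.0976,5
w2,11,0.0525,0.0461,6
w2,11.5,0.0119,-0.3733,5
w2,12,0.0457,-0.0204,3
w2,12.5,0.0046,-0.0204,0
w2,13,0.0018,-0.0324,0
w2,13.5,0.0027,0.0404,0
w2,14,0.0057,-1e-4,0
w2,14.5,0.0066,0.0508,0
w2,15,0.0034,-0.0313,0
w2,15.5,0.0077,0.052,0
w2,16,0.0078,0.0629,0
w2,16.5,0.0067,-0.0768,0
w2,17,0.008,-0.0393,0
w2,17.5,0.0069,0.0723,0
w2,18,0.0056,0.0106,0
w2,18.5,0.0031,0.0636,0
w2,19,0.0025,-0.0336,0
w2,19.5,0.0068,-0.0158,0
w2,20,0.0011,0.0063,0
w2,20.5,0.0041,-0.0216,0
w2,21,0.0047,-0.0599,0
w2,21.5,0.0075,-0.017,0
w2,22,0.005,-0.0631,0
w2,22.5,0.0047,0.0726,0
w2,23,0.0785,0.352,4
w2,23.5,0.0207,-0.2031,2
w2,24,0.1116,0.035,5
w2,24.5,0.1085,-0.1251,3
w2,25,0.0318,0.3545,6
w2,25.5,0.0131,0.3685,3
w2,26,0.0313,0.4006,4
w2,26.5,0.0022,-0.0128,0
w2,27,0.047,0.2082,4
w2,27.5,0.0385,0.3512,5
w2,28,0.0493,-0.1761,4
w2,28.5,0.0102,-0.4958,5
w2,29,0.0745,-0.5187,2
w2,29.5,0.0234,0.1649,4
w2,30,0.022,-0.3321,4
w2,30.5,0.0102,0.4622,4
w2,31,0.0259,-0.3519,5
w2,31.5,0.1075,0.1219,3
w2,32,0.0291,-0.199,5
w2,32.5,0.0483,-0.6593,6
w2,33,0.0371,0.3552,3
w2,33.5,0.0104,0.0416,5
w2,34,0.0475,0.3301,4
w2,34.5,0.0288,-0.4322,5
w2,35,0.026,0.3203,4
w2,35.5,0.0624,0.3307,4
w2,36,0.1603,-0.7236,4
w2,36.5,0.0179,-0.119,4
w2,37,0.0443,-0.3899,2
w2,37.5,0.0278,-0.5836,3
w2,38,0.0427,0.0774,3
w2,38.5,0.1287,0.2276,4
w2,39,0.0261,0.0311,6
w2,39.5,0.0012,0.0788,0
w2,40,0.0414,0.1221,4
w2,40.5,0.0586,0.0665,4
w2,41,0.0344,0.0083,3
w2,41.5,0.0291,-0.1525,6
w2,42,0.0289,0.1354,6
w2,42.5,0.0064,0.0113,0
w2,43,0.0031,0.0454,0
w2,43.5,0.0066,0.0647,0
w2,44,0.0055,0.0014,0
w2,44.5,0.0071,-0.0657,0
w2,45,9e-4,-0.0414,0
w2,45.5,0.0062,0.0489,0
w2,46,0.0421,-0.147,4
w2,46.5,0.0534,-0.5264,4
w2,47,0.005,-0.0442,0
w2,47.5,0.0022,0.0147,0
w2,48,0.0024,0.0687,0
w2,48.5,0.0028,0.0562,0
w2,49,0.0026,-0.0639,0
w2,49.5,0.0065,0.0653,0
w2,50,0.0022,0.0541,0
w2,50.5,0.0075,0.0525,0
w2,51,0.0072,-0.0639,0
w2,51.5,0.0014,-0.0541,0
w2,52,0.0064,0.0704,0
w2,52.5,7e-4,-0.0621,0
w2,53,0.0023,-0.0381,0
w2,53.5,0.0053,-0.0717,0
w2,54,0.0063,-0.0498,0
w2,54.5,0.0062,0.0059,0
w2,55,0.001,0.0109,0
w2,55.5,0.0599,0.2536,4
w2,56,0.0508,0.5038,5
w2,56.5,0.0152,0.4435,5
w2,57,0.0314,-0.0805,5
w2,57.5,0.0275,0.0989,5
w2,58,0.023,0.2087,3
w2,58.5,0.0214,0.2273,3
w2,59,0.0149,-0.0533,5
w2,59.5,0.0359,0.4311,0
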