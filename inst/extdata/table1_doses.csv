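region,unit,fbp_ramp,fbp_butterworth,fbp_hamming,fbp_hanning,fbp_parzen,fbp_3drp,osem2d_it1,osem2d_it2,osem2d_it3,osem2d_it4,osem2d_it5,osem2d_it6,osem2d_it7,osem2d_it8,osem2d_it9,osem2d_it10,map_beta_0.1,map_beta_1.0,map_beta_1.5
Tumor,mGy/MBq,1200,923,1020,1060,1020,1250,1320,1340,1440,1480,1560,1620,1660,1710,1760,1830,1380,1500,1180
Adrenals,mSv/MBq,0.0122,0.0094,0.0106,0.0104,0.0175,0.0121,0.0122,0.0140,0.0159,0.0175,0.0190,0.0206,0.0219,0.0227,0.0259,0.0911,0.0127,0.0141,0.0113
Brain,mSv/MBq,0.0327,0.0216,0.0222,0.0215,0.0556,0.0236,0.0263,0.0367,0.0466,0.0556,0.0642,0.0756,0.0775,0.0823,0.0899,0.3200,0.0233,0.0283,0.0207
Breasts,mSv/MBq,0.0036,0.0027,0.0031,0.0030,0.0053,0.0035,0.0037,0.0042,0.0048,0.0053,0.0057,0.0064,0.0066,0.0067,0.0077,0.0272,0.0036,0.0040,0.0033
Gallbladder wall,mSv/MBq,0.0107,0.0084,0.0093,0.0092,0.0147,0.0109,0.0105,0.0121,0.0135,0.0147,0.0158,0.0174,0.0180,0.0189,0.0211,0.0744,0.0110,0.0124,0.0096
Lower large intestine wall,mSv/MBq,0.0031,0.0023,0.0026,0.0026,0.0044,0.0031,0.0032,0.0036,0.0040,0.0044,0.0048,0.0053,0.0055,0.0058,0.0066,0.0231,0.0034,0.0038,0.0030
Small intestine,mSv/MBq,0.0041,0.0032,0.0036,0.0035,0.0057,0.0041,0.0041,0.0047,0.0052,0.0057,0.0062,0.0067,0.0071,0.0075,0.0084,0.0296,0.0043,0.0048,0.0038
Stomach wall,mSv/MBq,0.1060,0.0906,0.0947,0.0937,0.1230,0.1110,0.1010,0.1090,0.1160,0.1230,0.1300,0.1420,0.1440,0.1560,0.1820,0.6270,0.0993,0.1000,0.0925
Upper lower intestine wall,mSv/MBq,0.0046,0.0036,0.0040,0.0040,0.0063,0.0047,0.0046,0.0052,0.0058,0.0063,0.0069,0.0075,0.0078,0.0083,0.0093,0.0327,0.0048,0.0053,0.0043
Heart wall,mSv/MBq,0.0084,0.0064,0.0072,0.0071,0.0123,0.0084,0.0086,0.0097,0.0112,0.0123,0.0133,0.0148,0.0152,0.0155,0.0179,0.0629,0.0086,0.0094,0.0077
Kidneys,mSv/MBq,0.1890,0.1460,0.1650,0.1570,0.2680,0.1870,0.1800,0.2130,0.2420,0.2680,0.2930,0.2850,0.3390,0.3600,0.4040,1.4100,0.1830,0.2030,0.1720
Liver,mSv/MBq,0.0944,0.0746,0.0828,0.0821,0.1300,0.0979,0.0924,0.1070,0.1190,0.1300,0.1390,0.1550,0.1580,0.1660,0.1810,0.6440,0.0990,0.1130,0.0840
Lungs,mSv/MBq,0.1660,0.1240,0.1410,0.1390,0.2590,0.1630,0.1770,0.1980,0.2360,0.2590,0.2800,0.3140,0.3200,0.3220,0.3750,1.3200,0.1650,0.1790,0.1530
Muscle,mSv/MBq,0.0035,0.0027,0.0030,0.0030,0.0051,0.0035,0.0035,0.0041,0.0046,0.0051,0.0055,0.0061,0.0063,0.0066,0.0075,0.0264,0.0037,0.0040,0.0033
Ovaries,mSv/MBq,0.0031,0.0023,0.0027,0.0026,0.0045,0.0032,0.0032,0.0037,0.0041,0.0045,0.0049,0.0054,0.0057,0.0060,0.0067,0.0236,0.0035,0.0039,0.0031
Pancreas,mSv/MBq,0.0164,0.0127,0.0143,0.0141,0.0228,0.0162,0.0163,0.0187,0.0208,0.0228,0.0248,0.0276,0.0287,0.0297,0.0346,0.1210,0.0174,0.0190,0.0154
Red. Marrow,mSv/MBq,0.0038,0.0029,0.0033,0.0032,0.0056,0.0037,0.0038,0.0044,0.0051,0.0056,0.0062,0.0068,0.0071,0.0074,0.0084,0.0296,0.0039,0.0043,0.0035
Osteogenic,mSv/MBq,0.0031,0.0023,0.0026,0.0026,0.0047,0.0030,0.0031,0.0036,0.0042,0.0047,0.0051,0.0057,0.0059,0.0061,0.0070,0.0245,0.0031,0.0035,0.0028
Skin,mSv/MBq,0.0017,0.0013,0.0015,0.0014,0.0025,0.0017,0.0017,0.0020,0.0023,0.0025,0.0027,0.0030,0.0032,0.0033,0.0037,0.0131,0.0018,0.0019,0.0016
Spleen,mSv/MBq,0.4480,0.3260,0.3850,0.3820,0.6730,0.4120,0.4620,0.5380,0.6040,0.6730,0.7460,0.8620,0.8940,0.8990,1.0900,3.8000,0.5390,0.5960,0.4590
Thymus,mSv/MBq,0.0038,0.0029,0.0033,0.0032,0.0058,0.0038,0.0040,0.0045,0.0053,0.0058,0.0063,0.0070,0.0072,0.0073,0.0084,0.0296,0.0039,0.0042,0.0035
Thyroid,mSv/MBq,0.0014,0.0010,0.0011,0.0011,0.0021,0.0013,0.0014,0.0016,0.0019,0.0021,0.0023,0.0026,0.0027,0.0027,0.0031,0.0110,0.0013,0.0015,0.0012
Urinary bladder,mSv/MBq,0.1590,0.1140,0.1340,0.1320,0.2380,0.1600,0.1680,0.1940,0.2160,0.2380,0.2580,0.2890,0.2970,0.3160,0.3500,1.2300,0.1870,0.2120,0.1620
Uterus,mSv/MBq,0.0050,0.0037,0.0042,0.0042,0.0073,0.0050,0.0052,0.0060,0.0067,0.0073,0.0080,0.0089,0.0092,0.0097,0.0108,0.0381,0.0057,0.0064,0.0050
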