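dimension,section,term,estimate,se,p
GH,mean,(Intercept),0.8238,0.0415,<0.0001
GH,mean,Women,-0.2121,0.0267,<0.0001
GH,mean,Survey2003,-0.1393,0.0413,0.0007
GH,mean,Ager,-0.0349,0.0019,<0.0001
GH,mean,East,-0.2039,0.0480,<0.0001
GH,mean,West,0.1259,0.0344,0.0003
GH,mean,SouthWest,-0.0666,0.0301,0.0272
GH,mean,Ager:Women,0.0049,0.0013,0.0002
GH,mean,Ager:Survey2003,-0.0030,0.0018,0.1047
GH,mean,Ager:North_West,-0.0046,0.0013,0.0004
GH,mean,Ager:East,0.0062,0.0024,0.0096
GH,mean,Survey2003:North_EasternParisBasin,-0.1172,0.0233,<0.0001
GH,mean,Survey2003:WesternParisBasin_SouthEast,-0.0675,0.0266,0.0113
GH,variance,(Intercept),1.4130,0.0791,<0.0001
GH,variance,Survey2003,-0.1499,0.0837,0.0730
GH,variance,Ager,-0.0068,0.0034,0.0439
GH,variance,East,-0.2334,0.0513,<0.0001
GH,variance,SouthWest,-0.1254,0.0534,0.0188
GH,variance,Ager:Survey2003,0.0068,0.0037,0.0632
PF,mean,(Intercept),3.1131,0.0834,<0.0001
PF,mean,Women,-1.1154,0.0816,<0.0001
PF,mean,Survey2003,-0.2447,0.0512,<0.0001
PF,mean,Ager,-0.5960,0.0110,<0.0001
PF,mean,North,-0.2809,0.0696,<0.0001
PF,mean,WesternParisBasin,-0.1386,0.0723,0.0554
PF,mean,West_SouthWest_SouthEast,0.3284,0.0525,<0.0001
PF,mean,Women:Ager,0.0667,0.0127,<0.0001
PF,mean,Ager:North_EasternParisBasin_West_SouthWest_SouthEast,-0.0345,0.0079,<0.0001
PF,variance,(Intercept),8.9934,0.5003,<0.0001
PF,variance,Women,-2.4176,0.4027,<0.0001
PF,variance,Survey2003,3.0001,0.4436,<0.0001
PF,variance,Ager,-0.5758,0.0650,<0.0001
PF,variance,Women:Ager,0.1404,0.0533,0.0084
PF,variance,Survey2003:Ager,-0.2560,0.0595,<0.0001
MH,mean,(Intercept),0.5924,0.0313,<0.0001
MH,mean,Women,-0.4654,0.0186,<0.0001
MH,mean,Survey2003,-0.1824,0.0264,<0.0001
MH,mean,Ager,-0.0936,0.0076,<0.0001
MH,mean,North_WesternParisBasin,-0.1650,0.0319,<0.0001
MH,mean,East_EasternParisBasin,-0.0872,0.0238,0.0002
MH,mean,West_SouthWest,0.1110,0.0319,0.0005
MH,mean,Ager:North_West_SouthWest,-0.0425,0.0132,0.0005
MH,mean,Women:WesternParisBasin,0.1421,0.0552,0.0101
MH,variance,(Intercept),1.6797,0.0471,<0.0001
MH,variance,Ager,0.1080,0.0147,<0.0001
MH,variance,North_EasternParisBasin_WesternParisBasin_SouthEast,-0.1349,0.0530,0.0110
MH,variance,East_West_SouthWest,-0.2305,0.0562,<0.0001
MH,variance,MediterraneanBasin,0.1549,0.0792,0.0505
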