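time_min,glcnac1_mM,glcnac2_mM,glcnac3_mM,glcnac4_mM,glcnac5_mM,glcnac6_mM
5,0.6163900115836216,0.022990144911581155,0.03230485162180692,0.049917026329030355,0.32668865929864066,0.8178991771381147
10,1.2110408730672722,0.10889955356287283,0.0711003310401813,0.07647693417400413,0.3981735878505711,0.5934844440542637
15,1.7510654160072041,0.22075011061806502,0.08955040422855133,0.08317348635902527,0.3989513149684817,0.4518637428395261
30,3.0202229771316746,0.5357160288391188,0.08707530396431017,0.06915675150589262,0.30465451604433896,0.224520997209765
60,4.44612452761165,0.8712258309001633,0.042726900698225004,0.03137095938290676,0.1318911557089848,0.06637776594642897
120,5.479123796741042,0.9234998109987221,0.006512792982726681,0.004597686370991939,0.018834423351398195,0.006961454217008113
180,5.892847867074966,0.7926372254504072,8.582740120294427e-4,5.985298468574299e-4,0.0024317434791147827,7.912988210175341e-4
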