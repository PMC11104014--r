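table,run,m_R1,b_R1,r_R1,m_R2,b_R2,r_R2
1,1,1.0184,-1.2667,0.9990,0.9861,8.4143,0.9604
1,2,0.9946,-1.1662,0.9992,0.9738,8.1196,0.9698
1,3,0.9973,-0.7747,0.9993,0.9729,8.5935,0.9664
1,4,0.9909,-3.3821,0.9933,0.9901,5.5440,0.9839
1,5,1.0311,-0.3799,0.9976,0.9880,9.5944,0.9477
1,6,0.9706,-1.6504,0.9948,0.9657,7.1596,0.9812
1,7,1.0590,0.8696,0.9896,0.9943,11.4469,0.9211
1,8,0.9735,-2.7446,0.9933,0.9735,6.0116,0.9848
1,9,1.0163,-0.9341,0.9992,0.9847,8.7232,0.9596
1,10,1.0296,-0.7564,0.9974,0.9909,9.1348,0.9515
2,1,1.0606,-6.1192,0.9763,0.8391,24.1075,0.9706
2,2,0.8794,-4.5956,0.9751,0.6966,20.4377,0.9707
2,3,1.0769,-4.4772,0.9790,0.8454,26.4352,0.9658
2,4,0.9266,-4.2082,0.9842,0.7338,22.1728,0.9796
2,5,0.9220,-5.9269,0.9785,0.7317,20.2775,0.9758
2,6,1.0330,-2.6378,0.9819,0.8133,26.9357,0.9715
2,7,1.0117,-3.7888,0.9852,0.7935,25.2762,0.9711
2,8,0.9541,-5.0865,0.9845,0.7559,22.0701,0.9802
2,9,1.0255,-7.0626,0.9852,0.8121,22.1242,0.9805
2,10,1.0546,-3.7976,0.9813,0.8272,26.4984,0.9673
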