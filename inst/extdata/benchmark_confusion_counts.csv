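ensemble,method,tp,tn,fp,fn,published_acc,published_dc
E(0.1%Np),mean,53070,345006,13060,26364,0.910,0.648
E(1%Np),mean,64352,340931,17135,15082,0.926,0.781
E(10%Np),mean,65777,340942,17124,13657,0.930,0.792
"E(0.1%Np,pru)",mean,53502,344567,13499,25932,0.910,0.652
"E(1%Np,pru)",mean,64737,340934,17132,14697,0.927,0.785
"E(10%Np,pru)",mean,65718,341135,16931,13716,0.930,0.793
E(Ntr),mean,65421,342518,15548,14013,0.932,0.792
"E(Ntr,80%pru)",mean,65371,342453,15613,14063,0.932,0.792
E(0.1%Np),median,54688,343419,14647,24746,0.910,0.660
E(1%Np),median,65002,340030,18036,14432,0.926,0.783
E(10%Np),median,66038,340651,17415,13396,0.930,0.793
"E(0.1%Np,pru)",median,55126,343027,15039,24308,0.910,0.664
"E(1%Np,pru)",median,65307,339963,18103,14127,0.926,0.785
"E(10%Np,pru)",median,65961,340781,17285,13473,0.930,0.793
E(Ntr),median,66012,341807,16259,13422,0.932,0.795
"E(Ntr,80%pru)",median,65937,341805,16261,13497,0.932,0.794
E(0.1%Np),alpha,51328,346449,11617,28106,0.909,0.637
E(1%Np),alpha,63186,342245,15821,16248,0.927,0.777
E(10%Np),alpha,65059,341723,16343,14375,0.930,0.790
"E(0.1%Np,pru)",alpha,51774,346081,11985,27660,0.909,0.641
"E(1%Np,pru)",alpha,63536,342242,15824,15898,0.927,0.781
"E(10%Np,pru)",alpha,64963,341967,16099,14471,0.930,0.790
E(Ntr),alpha,63896,343992,14074,15538,0.932,0.787
"E(Ntr,80%pru)",alpha,63611,344017,14049,15823,0.932,0.785
E(0.1%Np),majority,54813,343261,14805,24621,0.910,0.660
E(1%Np),majority,65121,339891,18175,14313,0.926,0.784
E(10%Np),majority,66107,340553,17513,13327,0.930,0.793
"E(0.1%Np,pru)",majority,55126,343027,15039,24308,0.910,0.664
"E(1%Np,pru)",majority,65307,339963,18103,14127,0.926,0.785
"E(10%Np,pru)",majority,65961,340781,17285,13473,0.930,0.793
E(Ntr),majority,66111,341669,16397,13323,0.932,0.795
"E(Ntr,80%pru)",majority,66029,341700,16366,13405,0.932,0.785
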