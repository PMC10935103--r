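scope,label,nee_mean,nee_sd,re_mean,re_sd,gep_mean,gep_sd
period,FG_ON,-17.30,9.58,26.24,4.04,43.54,8.65
period,LS_ON,-19.04,11.77,29.08,4.90,48.12,12.84
period,NF_ON,-12.19,11.42,21.48,4.82,34.12,12.36
period,LR_OFF,-11.75,12.77,26.53,6.32,38.28,13.24
period,LS_OFF,-23.85,12.61,26.39,6.55,50.24,16.15
period,NF_OFF,-3.37,8.24,22.01,4.45,25.38,8.56
annual,on,-1071.99,,1799.41,,2871.40,
annual,off,-1051.70,,1777.79,,2829.49,
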