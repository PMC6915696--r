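table,label,mean_q,sd_q,printed_cv_percent,printed_re_percent
1,avgQ48a_1600,48.44,0.36,0.75,1.01
1,avgQ48a_1280,48.29,1.27,2.63,0.69
1,avgQ48a_960,51.01,1.67,3.28,6.36
1,avgQ48a_640,51.14,1.41,2.76,6.63
1,avgQ48a_320,53.90,0.99,1.83,12.39
2,avgQ48a,51.75,1.75,3.37,7.90
2,avgQ48b,50.71,0.22,0.44,5.75
2,avgQ48c,50.28,1.68,3.34,4.90
3,avgQ38,42.26,1.50,3.55,11.20
3,avgQ40.5,44.69,1.29,2.89,10.38
3,avgQ43,48.48,0.51,1.05,12.74
3,avgQ45.5,49.54,1.08,2.19,8.93
3,avgQ50.5,54.08,1.71,3.17,7.12
3,avgQ53,56.09,1.36,2.43,5.84
3,avgQ55.5,59.52,0.14,0.23,7.21
3,avgQ58,60.94,1.51,2.53,5.06
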