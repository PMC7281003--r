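herd,n,location,parity_mean,parity_sd,dim_mean,dim_sd,bhba_mean,bhba_sd
1,129,Sth Gipp,2.9,1.1,19.4,7.2,1.25,0.69
2,11,Sth Gipp,2.6,1.2,20.4,8.1,0.34,0.12
3,12,W Gipp,2.6,1.4,22.8,5.7,0.33,0.10
4,11,W Gipp,3.1,1.2,17.9,10.2,0.54,0.15
5,18,MID,2.9,1.1,22.6,5.1,0.61,0.25
6,248,W Gipp,2.1,1.0,16.7,6.0,0.55,0.21
7,9,GV,2.6,1.0,13.9,6.7,0.53,0.27
8,24,MID,2.4,1.2,17.7,8.2,0.38,0.09
9,33,Sth Gipp,2.5,1.2,18.3,7.2,0.55,0.33
10,27,Sth Gipp,1.8,1.1,13.1,7.7,0.50,0.14
11,50,Tas,2.6,1.3,18.6,7.3,0.42,0.17
12,123,MID,2.8,1.2,15.8,8.6,0.38,0.15
13,12,Tas,2.7,0.8,16.0,7.6,0.58,0.22
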