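technique,feature_set,class,precision,support
rf,original,0,0.91,7951
rf,original,1,0.99,7448
rf,original,2,0.94,7386
rf,original,3,0.98,6484
rf,original,4,0.93,6273
rf,original,5,0.96,6711
rf,original,6,0.98,6692
rf,original,7,1.00,6380
dt,original,0,0.88,7951
dt,original,1,0.85,7448
dt,original,2,0.87,7386
dt,original,3,0.86,6484
dt,original,4,0.91,6273
dt,original,5,0.77,6711
dt,original,6,0.94,6692
dt,original,7,0.99,6380
gnb,original,0,0.41,7951
gnb,original,1,0.28,7448
gnb,original,2,0.52,7386
gnb,original,3,0.46,6484
gnb,original,4,0.39,6273
gnb,original,5,0.45,6711
gnb,original,6,0.32,6692
gnb,original,7,0.52,6380
lr,original,0,0.39,7951
lr,original,1,0.47,7448
lr,original,2,0.29,7386
lr,original,3,0.04,6484
lr,original,4,0.16,6273
lr,original,5,0.31,6711
lr,original,6,0.08,6692
lr,original,7,0.48,6380
lstm,original,0,0.84,7951
lstm,original,1,0.90,7448
lstm,original,2,0.86,7386
lstm,original,3,0.93,6484
lstm,original,4,0.86,6273
lstm,original,5,0.89,6711
lstm,original,6,0.88,6692
lstm,original,7,0.94,6380
rf,transfer,0,0.99,7951
rf,transfer,1,1.00,7448
rf,transfer,2,0.99,7386
rf,transfer,3,0.99,6484
rf,transfer,4,0.98,6273
rf,transfer,5,1.00,6711
rf,transfer,6,0.99,6692
rf,transfer,7,1.00,6380
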