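model,subject,accuracy,kappa
eegnet,S1,84.34,0.79
eegnet,S2,54.06,0.39
eegnet,S3,87.54,0.83
eegnet,S4,63.59,0.51
eegnet,S5,67.39,0.57
eegnet,S6,54.88,0.39
eegnet,S7,88.80,0.85
eegnet,S8,76.75,0.69
eegnet,S9,74.24,0.65
mbeegnet,S1,89.59,0.86
mbeegnet,S2,68.06,0.57
mbeegnet,S3,94.58,0.93
mbeegnet,S4,79.88,0.73
mbeegnet,S5,76.92,0.69
mbeegnet,S6,66.10,0.55
mbeegnet,S7,91.57,0.89
mbeegnet,S8,87.71,0.84
mbeegnet,S9,83.69,0.78
shallowconvnet,S1,79.51,0.73
shallowconvnet,S2,56.25,0.42
shallowconvnet,S3,88.89,0.85
shallowconvnet,S4,80.90,0.75
shallowconvnet,S5,57.29,0.43
shallowconvnet,S6,53.28,0.38
shallowconvnet,S7,91.67,0.89
shallowconvnet,S8,81.25,0.75
shallowconvnet,S9,79.17,0.72
mb_shallowconvnet,S1,82.58,0.77
mb_shallowconvnet,S2,70.01,0.60
mb_shallowconvnet,S3,93.79,0.92
mb_shallowconvnet,S4,82.60,0.77
mb_shallowconvnet,S5,77.81,0.70
mb_shallowconvnet,S6,64.79,0.53
mb_shallowconvnet,S7,88.02,0.84
mb_shallowconvnet,S8,86.91,0.83
mb_shallowconvnet,S9,83.83,0.78
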