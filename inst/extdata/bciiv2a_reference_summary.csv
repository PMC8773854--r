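model,mean_accuracy,sd_accuracy,mean_kappa,sd_kappa
eegnet,72.40,13.27,0.63,0.18
mbeegnet,82.01,10.13,0.76,0.13
shallowconvnet,74.31,14.54,0.66,0.19
mb_shallowconvnet,81.15,9.04,0.75,0.12
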