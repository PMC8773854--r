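model,subject,accuracy
eegnet,1,94.37
eegnet,2,92.50
eegnet,3,100
eegnet,4,96.25
eegnet,5,96.87
eegnet,6,98.12
eegnet,7,93.07
eegnet,8,96.87
eegnet,9,98.12
eegnet,10,91.25
eegnet,11,80.00
eegnet,12,96.25
eegnet,13,95.60
eegnet,14,79.37
mbeegnet,1,95.02
mbeegnet,2,95.02
mbeegnet,3,100
mbeegnet,4,99.40
mbeegnet,5,98.17
mbeegnet,6,98.80
mbeegnet,7,93.13
mbeegnet,8,95.52
mbeegnet,9,98.18
mbeegnet,10,92.14
mbeegnet,11,89.43
mbeegnet,12,96.02
mbeegnet,13,94.45
mbeegnet,14,88.88
shallowconvnet,1,96.87
shallowconvnet,2,93.75
shallowconvnet,3,99.37
shallowconvnet,4,98.12
shallowconvnet,5,98.12
shallowconvnet,6,93.12
shallowconvnet,7,92.45
shallowconvnet,8,96.87
shallowconvnet,9,98.12
shallowconvnet,10,90.62
shallowconvnet,11,76.25
shallowconvnet,12,95.00
shallowconvnet,13,94.96
shallowconvnet,14,91.25
mb_shallowconvnet,1,98.25
mb_shallowconvnet,2,96.23
mb_shallowconvnet,3,98.80
mb_shallowconvnet,4,98.18
mb_shallowconvnet,5,97.65
mb_shallowconvnet,6,96.90
mb_shallowconvnet,7,93.80
mb_shallowconvnet,8,97.00
mb_shallowconvnet,9,97.52
mb_shallowconvnet,10,92.50
mb_shallowconvnet,11,80.78
mb_shallowconvnet,12,96.25
mb_shallowconvnet,13,95.62
mb_shallowconvnet,14,92.04
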