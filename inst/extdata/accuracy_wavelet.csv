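classifier,space,c1,avg_printed
NB,gray,67.62,67.62
NB,lab,66.67,66.67
NB,opponent,62.86,62.86
LMT,gray,67.62,67.62
LMT,lab,80.95,80.95
LMT,opponent,76.19,76.19
RT,gray,73.33,73.33
RT,lab,71.43,71.43
RT,opponent,65.71,65.71
RF,gray,75.24,75.24
RF,lab,86.67,86.67
RF,opponent,70.48,70.48
SVM,gray,85.71,85.71
SVM,lab,88.57,88.57
SVM,opponent,84.76,84.76
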