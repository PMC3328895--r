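method,space,ss_between,df_between,ms_between,F,p_below_alpha,ss_within,df_within,ms_within,ss_total,df_total,excluded,ss_between_typo
butterworth,gray,976.06,4,244.02,3.74,TRUE,2611.87,40,65.30,3587.93,44,,FALSE
butterworth,lab,1097.44,4,274.36,2.56,FALSE,4287.01,40,107.18,5384.45,44,,FALSE
butterworth,opponent,1640.57,4,410.14,8.16,TRUE,2009.93,40,50.25,3650.50,44,,FALSE
cooccurrence,gray,1165.72,4,291.43,18.29,TRUE,477.98,30,15.93,1643.71,34,,FALSE
cooccurrence,lab,135.20,4,331.30,29.18,TRUE,340.63,30,11.35,1665.83,34,,TRUE
cooccurrence,opponent,1778.14,4,444.53,31.13,TRUE,428.42,30,14.28,2206.56,34,,FALSE
markov,gray,8574.66,4,2143.67,109.52,TRUE,880.82,45,19.57,9455.48,49,,FALSE
markov,lab,4352.63,3,1450.88,47.11,TRUE,1108.76,36,30.80,5461.39,39,NB,FALSE
markov,opponent,3251.16,3,1083.72,33.36,TRUE,1169.32,36,32.48,4420.47,39,NB,FALSE
gabor,gray,1732.62,4,433.15,95.67,TRUE,67.92,15,4.53,1800.53,19,,FALSE
gabor,lab,1071.28,3,357.09,24.58,TRUE,174.31,12,14.53,1245.59,15,NB,FALSE
gabor,opponent,457.58,3,152.52,13.68,TRUE,133.81,12,11.15,591.39,15,SVM,FALSE
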