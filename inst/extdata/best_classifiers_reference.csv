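method,space,best_set,no_significant_differences
butterworth,gray,SVM;LMT;RF,FALSE
butterworth,lab,,TRUE
butterworth,opponent,SVM;LMT,FALSE
cooccurrence,gray,SVM,FALSE
cooccurrence,lab,SVM,FALSE
cooccurrence,opponent,SVM,FALSE
markov,gray,SVM,FALSE
markov,lab,SVM,FALSE
markov,opponent,SVM,FALSE
gabor,gray,SVM,FALSE
gabor,lab,SVM,FALSE
gabor,opponent,LMT;RF,FALSE
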