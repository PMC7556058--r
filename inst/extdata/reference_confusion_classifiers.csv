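classifier,predicted,high,medium,low
decision_tree,high,30,10,1
decision_tree,medium,16,52,0
decision_tree,low,10,2,47
naive_bayes,high,40,8,5
naive_bayes,medium,8,56,4
naive_bayes,low,8,0,39
svm_rbf,high,46,2,4
svm_rbf,medium,0,60,4
svm_rbf,low,10,2,40
mlp_ann,high,49,2,7
mlp_ann,medium,4,58,4
mlp_ann,low,3,4,45
nhl_fcm,high,55,1,1
nhl_fcm,medium,1,60,1
nhl_fcm,low,0,3,46
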