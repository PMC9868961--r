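model_id,closeness,rank
Random_forest,0.961423,1
ANN1_logistic,0.789202,2
ANN1_ReLu,0.69774,3
ANN1_tanh,0.602147,4
ANN2_tanh,0.516367,5
SVM_linear,0.482942,6
ANN2_logistic,0.447746,7
SVM_polynomial,0.386691,8
SVM_rbf,0.327762,9
SVM_sigmoid,0.276047,10
ANN2_ReLu,0.166041,11
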