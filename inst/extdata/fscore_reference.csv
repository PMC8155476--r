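method,n_features,f_n,f_a,f_o,f_p,f_mean
LR_RF,52,0.896,0.742,0.719,0.534,0.722
PT_RF,56,0.899,0.740,0.730,0.596,0.741
RF_RF,41,0.898,0.751,0.728,0.580,0.739
SHAP_RF,28,0.900,0.768,0.733,0.579,0.745
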