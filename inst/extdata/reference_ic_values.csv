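cohort,model,minus2LL,AIC,w_AIC,AICc,w_AICc,BIC,w_BIC,n,N
control,generalized_logistic,5159.69,5179.69,0.0037,5180.07,0.0038,5190.13,0.0038,386,21
control,gompertz,5182.79,5198.79,2.66E-07,5199.01,2.88E-07,5207.15,7.72E-07,386,21
control,von_bertalanffy,5189.97,5209.97,9.94E-10,5210.35,9.95E-10,5226.42,5.05E-11,386,21
control,simeoni,5148.52,5168.52,0.9963,5168.90,0.9963,5179.01,0.9962,386,21
treated,simeoni-1,6786.12,6818.12,0.015,6818.91,0.016,6833.23,0.020,545,19
treated,simeoni-2,6780.10,6812.10,0.310,6812.89,0.325,6827.21,0.410,545,19
treated,simeoni-3,6780.32,6812.32,0.278,6813.11,0.291,6827.44,0.366,545,19
treated,delay,6775.61,6811.61,0.397,6812.64,0.368,6828.61,0.204,545,19
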