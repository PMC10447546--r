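stratum,dimension,mse,mse_sd,rmse,rmse_sd,mape,mape_sd,mae,mae_sd
female,horizontal,10.38,10.36,3.22,1.68,2.84,1.73,2.76,1.68
male,horizontal,13.41,11.61,3.66,1.85,3.14,1.84,3.19,1.85
female,vertical,11.31,10.58,3.36,1.76,4.25,2.58,2.87,1.76
male,vertical,15.70,12.44,3.96,1.79,4.83,2.44,3.56,1.79
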