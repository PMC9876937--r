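group,variable,n,mean,sd,min,max
forest,mass_before_g,7,371.4,27.0,NA,NA
urban,mass_before_g,13,334.2,19.0,NA,NA
forest,mass_after_g,7,376.3,19.5,NA,NA
urban,mass_after_g,13,343.8,21.1,NA,NA
forest,time_outside_h,7,3.1,2.5,NA,NA
urban,time_outside_h,13,4.7,2.1,NA,NA
forest,rmr_ml_o2_h,22,173.52,67.85,84.50,232.09
urban,rmr_ml_o2_h,35,149.84,44.40,109.35,202.99
forest,rmr_kj_h,22,3.54,1.38,1.72,4.73
urban,rmr_kj_h,35,3.05,0.90,2.23,4.14
forest,rmr_ml_o2_h_g,22,0.48,0.18,0.24,0.64
urban,rmr_ml_o2_h_g,35,0.44,0.13,0.33,0.52
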