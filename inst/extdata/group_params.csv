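feature,group,mean,se,n,mode,source
vmax_S22,1c,12.67,1.471,7,steady,paper
vmax_S22,1d,8.33,0.766,5,steady,paper
vmax_S22,1c,12.06,1.326,7,transient,paper
vmax_S22,1d,8.13,0.666,5,transient,paper
area_S3,2c,0.12,0.009,10,any,paper
area_S3,2d,0.09,0.005,9,any,paper
area_S6,2c,0.10,0.008,10,any,paper
area_S6,2d,0.07,0.004,9,any,paper
area_S1,2c,0.06,0.006,10,any,paper
area_S1,2d,0.10,0.016,9,any,paper
angle_2,2c,67.60,2.663,10,any,paper
angle_2,2d,60.22,2.783,9,any,paper
R_5_6,2c,57.18,4.679,10,steady,paper
R_5_6,2d,97.64,15.565,9,steady,paper
R_5_6,2c,60.95,5.893,10,transient,paper
R_5_6,2d,99.24,14.945,9,transient,paper
vmax_S1,2c,15.22,0.919,10,steady,paper
vmax_S1,2d,9.98,1.091,9,steady,paper
vmax_S1,2c,14.22,0.649,10,transient,paper
vmax_S1,2d,9.59,1.038,9,transient,paper
vmax_S15,2c,25.96,5.461,10,steady,paper
vmax_S15,2d,9.49,1.406,9,steady,paper
vmax_S15,2c,24.77,4.851,10,transient,paper
vmax_S15,2d,9.02,1.396,9,transient,paper
vmax_S13,2c,9.45,1.230,10,steady,paper
vmax_S13,2d,17.89,4.230,9,steady,paper
vmax_S13,2c,9.04,1.129,10,transient,paper
vmax_S13,2d,16.79,3.880,9,transient,paper
vmax_S16,2c,15.55,2.790,10,steady,paper
vmax_S16,2d,9.05,1.854,9,steady,paper
vmax_S16,2c,15.01,2.456,10,transient,paper
vmax_S16,2d,8.84,1.782,9,transient,paper
Q_15_16,2c,4.70,0.001,10,steady,paper
Q_15_16,2d,2.60,0.001,9,steady,paper
Q_15_16,2c,4.52,0.001,10,transient,paper
Q_15_16,2d,2.45,0.0004,9,transient,paper
vel_CCA_L,1c,12.0,0.96,7,any,placeholder
vel_CCA_L,1d,9.6,0.768,5,any,placeholder
vel_CCA_L,2c,12.0,0.96,10,any,placeholder
vel_CCA_L,2d,12.0,0.96,9,any,placeholder
vel_CCA_R,1c,12.0,0.96,7,any,placeholder
vel_CCA_R,1d,9.6,0.768,5,any,placeholder
vel_CCA_R,2c,12.0,0.96,10,any,placeholder
vel_CCA_R,2d,9.2,0.736,9,any,placeholder
vel_VA_L,1c,7.0,0.56,7,any,placeholder
vel_VA_L,1d,7.0,0.56,5,any,placeholder
vel_VA_L,2c,7.0,0.56,10,any,placeholder
vel_VA_L,2d,7.0,0.56,9,any,placeholder
vel_VA_R,1c,7.0,0.56,7,any,placeholder
vel_VA_R,1d,7.0,0.56,5,any,placeholder
vel_VA_R,2c,7.0,0.56,10,any,placeholder
vel_VA_R,2d,7.0,0.56,9,any,placeholder
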