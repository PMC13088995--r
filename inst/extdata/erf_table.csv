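disease_id,pollutant,form,theta,theta_se,alpha,mu,nu,z_cf,beta,beta_se,c0,per_unit,min_age,age_band,note
stroke,PM2.5,GEMM,0.2720,0.07697,6.2,16.7,23.7,2.4,,,,,25,,GEMM stroke
LC,PM2.5,GEMM,0.2942,0.06147,6.2,9.3,29.8,2.4,,,,,25,,GEMM lung cancer
LRI,PM2.5,GEMM,0.4468,0.11735,6.4,5.7,8.4,2.4,,,,,0,,GEMM lower respiratory infections (all ages)
COPD,PM2.5,GEMM,0.2510,0.06762,6.5,2.5,32.0,2.4,,,,,25,,GEMM COPD
IHD,PM2.5,GEMM,0.2969,0.01787,1.9,12.0,40.2,2.4,,,,,25,,GEMM ischemic heart disease
T2DM,PM2.5,GEMM,0.1000,0.0200,1.6,15.5,36.8,2.4,,,,,25,,synthetic GEMM-form extension (T2DM not in the original GEMM causes)
CCVD-CO,CO,log-linear,,,,,,,0.008,0.002,0,1000,0,,placeholder beta per 1 mg/m3
RD-NO2,NO2,log-linear,,,,,,,0.020,0.005,0,10,0,,placeholder beta per 10 ug/m3
CCVD-SO2,SO2,log-linear,,,,,,,0.015,0.004,0,10,0,,placeholder beta per 10 ug/m3
RD-SO2,SO2,log-linear,,,,,,,0.018,0.0045,0,10,0,,placeholder beta per 10 ug/m3
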