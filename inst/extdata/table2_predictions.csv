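# Published regression-prediction benchmark. Training rows carry the
# simulated-permeability input actually fed to the calibration line (these
# occasionally differ in the last digit from the kinetics table), the
# experimental apparent permeability used for scoring (nicotine uses the
# 1.73e-4 variant here, vs 1.78e-4 in the reference table), the published
# prediction and the published order-of-magnitude error. The training_167C
# rows use the full-precision 167 C line (m = 1.124, c = -4.819); the
# training_127C rows use the 127 C line (m = 1.17, c = -3.73). Validation
# rows are provenance-only: their simulated inputs come from a supplement
# that is not packaged, so they are never recomputed. All values cm/s
# except the dimensionless error.
dataset,compound,P_sim_input,P_app_exp,prediction_printed,oom_error_printed
validation,Sertraline,NA,2.10e-6,1.67e-6,1.25000
validation,Risperdal,NA,3.00e-5,5.24e-5,0.24000
validation,Diazepam,NA,4.60e-5,5.27e-5,0.94000
validation,Lacosamide,NA,1.60e-5,1.02e-4,0.81000
training_167C,Ethanol,8.99e0,1.10e-3,1.79e-4,0.78837
training_167C,Nicotine,9.85e0,1.73e-4,1.98e-4,0.05958
training_167C,Bupropion,1.56e0,4.75e-5,2.50e-5,0.27862
training_167C,Dilantin,2.89e0,2.70e-5,5.00e-5,0.26769
training_167C,Caffeine,9.00e-2,2.10e-5,1.01e-6,1.31665
training_167C,Glycerol,1.20e-1,9.50e-6,1.40e-6,0.83172
training_167C,Temozolomide,1.30e-1,1.86e-6,1.53e-6,0.08444
training_167C,Atenolol,7.00e-1,1.30e-6,1.02e-5,0.89295
training_167C,Doxorubicin,7.00e-2,1.00e-7,7.64e-7,0.88289
training_127C,Propanol,3.73e0,3.30e-3,8.69e-4,0.57961
training_127C,Ethanol,3.08e0,1.10e-3,6.94e-4,0.20028
training_127C,Nicotine,2.51e0,1.73e-4,5.47e-4,0.49977
training_127C,Ketoprofen,2.11e-1,8.00e-5,3.02e-5,0.42368
training_127C,Bupropion,7.40e-2,4.75e-5,8.85e-6,0.72969
training_127C,Dilantin,1.83e-1,2.70e-5,2.55e-5,0.02430
training_127C,Duloxetine,5.72e-2,1.66e-5,6.55e-6,0.40395
training_127C,Atenolol,7.73e-2,1.30e-6,9.31e-6,0.85523
training_127C,Nadolol,1.20e-1,1.00e-7,1.56e-5,2.19264
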