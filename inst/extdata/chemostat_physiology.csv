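parameter,control,treated,control_sd,treated_sd,units
mu_batch,0.38,0.37,0.02,0.03,1/h
residual_glucose,0.69,0.69,0.05,0.22,g/L
q_glucose,-5.80,-7.34,0.05,0.50,mmol/gDW/h
q_co2,9.82,11.04,1.01,1.03,mmol/gDW/h
q_ethanol,8.66,13.27,0.34,1.17,mmol/gDW/h
q_glycerol,1.04,0.84,0.07,0.24,mmol/gDW/h
q_lactate,0.08,0.06,0.00,0.03,mmol/gDW/h
q_pyruvate,0.02,0.03,0.00,0.02,mmol/gDW/h
q_acetate,0.00,0.00,0.00,0.00,mmol/gDW/h
X,2.64,2.14,0.01,0.02,gDW/L
Y_XS,0.13,0.09,0.00,0.00,gDW/g
Y_EthS,0.38,0.46,0.02,0.01,g/g
C_recovery,98.5,100.7,3.3,0.1,%
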