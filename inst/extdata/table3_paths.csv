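variable,role,xm_mean,xm_lo,xm_hi,my_mean,my_lo,my_hi,value_mean,value_lo,value_hi
pain,mediator,-1.18,-1.28,-1.08,-0.07,-0.21,0.07,0.09,-0.08,0.25
alcohol_use,mediator,-0.47,-0.58,-0.37,-0.37,-0.53,-0.21,0.17,0.09,0.26
disability,mediator,0.70,0.61,0.79,0.14,0.01,0.27,0.10,0.01,0.19
smoking,mediator,-0.08,-0.18,0.02,-0.45,-0.61,-0.29,0.04,-0.01,0.09
health_status,mediator,-1.33,-1.42,-1.24,-0.68,-0.85,-0.52,0.90,0.67,1.13
satisfaction_health,mediator,-1.33,-1.42,-1.23,-0.27,-0.41,-0.13,0.36,0.18,0.56
adl,mediator,0.99,0.90,1.08,0.22,0.09,0.34,0.21,0.09,0.34
chronic_disease,mediator,0.80,0.69,0.90,0.71,0.51,0.91,0.56,0.39,0.74
total_indirect,total_indirect,NA,NA,NA,NA,NA,NA,2.43,2.10,2.76
direct,direct,NA,NA,NA,NA,NA,NA,0.17,0.04,0.31
total,total,NA,NA,NA,NA,NA,NA,2.60,NA,NA
proportion_mediated,proportion_mediated,NA,NA,NA,NA,NA,NA,93.46,NA,NA
health_insurance,control,NA,NA,NA,NA,NA,NA,1.22,0.68,1.79
physical_examination,control,NA,NA,NA,NA,NA,NA,0.32,0.19,0.45
marital_status,control,NA,NA,NA,NA,NA,NA,-0.04,-0.20,0.13
work_status,control,NA,NA,NA,NA,NA,NA,-0.30,-0.44,-0.16
residence,control,NA,NA,NA,NA,NA,NA,-0.14,-0.28,0.02
satisfaction_healthcare,control,NA,NA,NA,NA,NA,NA,0.02,-0.10,0.14
age,control,NA,NA,NA,NA,NA,NA,0.35,0.20,0.51
gender,control,NA,NA,NA,NA,NA,NA,0.45,0.30,0.60
ethnicity,control,NA,NA,NA,NA,NA,NA,0.02,-0.22,0.28
pension,control,NA,NA,NA,NA,NA,NA,0.10,-0.13,0.33
education,control,NA,NA,NA,NA,NA,NA,-0.10,-0.31,0.10
religious_belief,control,NA,NA,NA,NA,NA,NA,-0.12,-0.32,0.07
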