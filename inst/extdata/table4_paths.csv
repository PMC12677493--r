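variable,role,xm_mean,xm_lo,xm_hi,my_mean,my_lo,my_hi,value_mean,value_lo,value_hi
alcohol_use,mediator,-0.48,-0.59,-0.37,-0.41,-0.57,-0.26,0.20,0.11,0.29
disability,mediator,0.70,0.60,0.79,0.13,0.00,0.26,0.09,0.00,0.18
health_status,mediator,-1.33,-1.42,-1.23,-0.67,-0.83,-0.50,0.89,0.66,1.11
satisfaction_health,mediator,-1.33,-1.42,-1.23,-0.28,-0.41,-0.14,0.37,0.18,0.54
adl,mediator,0.99,0.89,1.08,0.19,0.07,0.32,0.19,0.07,0.32
chronic_disease,mediator,0.80,0.69,0.90,0.74,0.54,0.94,0.59,0.42,0.77
total_indirect,total_indirect,NA,NA,NA,NA,NA,NA,2.32,2.02,2.62
direct,direct,NA,NA,NA,NA,NA,NA,0.16,0.02,0.29
total,total,NA,NA,NA,NA,NA,NA,2.48,NA,NA
proportion_mediated,proportion_mediated,NA,NA,NA,NA,NA,NA,93.55,NA,NA
health_insurance,control,NA,NA,NA,NA,NA,NA,1.28,0.78,1.86
physical_examination,control,NA,NA,NA,NA,NA,NA,0.34,0.21,0.47
work_status,control,NA,NA,NA,NA,NA,NA,-0.36,-0.49,-0.23
age,control,NA,NA,NA,NA,NA,NA,0.37,0.23,0.52
gender,control,NA,NA,NA,NA,NA,NA,0.28,0.14,0.40
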