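indicator,units,lower_male,upper_male,lower_female,upper_female,risk_direction,plaus_lower,plaus_upper,scale_max
WC,cm,NA,90,NA,85,high_is_risk,40,200,NA
WHR,ratio,NA,0.90,NA,0.85,high_is_risk,0.3,1.8,NA
SBP,mmHg,NA,130,NA,130,high_is_risk,50,300,NA
DBP,mmHg,NA,85,NA,85,high_is_risk,30,200,NA
TG,mmol/L,NA,1.70,NA,1.70,high_is_risk,0.05,30,NA
HDLC,mmol/L,1.04,NA,1.04,NA,low_is_risk,0.1,5,NA
LDLC,mmol/L,NA,3.37,NA,3.37,high_is_risk,0.1,15,NA
BMI,kg/m^2,NA,24,NA,24,high_is_risk,10,60,NA
TC,mmol/L,NA,5.2,NA,5.2,high_is_risk,1,15,NA
FGLU,mmol/L,NA,6.1,NA,6.1,high_is_risk,1,40,NA
UA,umol/L,NA,420,NA,360,high_is_risk,50,1500,NA
ALT,U/L,NA,40,NA,40,high_is_risk,1,1000,NA
AST,U/L,NA,40,NA,40,high_is_risk,1,1000,NA
HGB,g/L,NA,175,NA,150,high_is_risk,30,250,NA
RBC,10^12/L,NA,5.8,NA,5.1,high_is_risk,1,10,NA
WBC,10^9/L,NA,9.5,NA,9.5,high_is_risk,0.5,100,NA
PLT,10^9/L,NA,350,NA,350,high_is_risk,10,1500,NA
CR,umol/L,NA,104,NA,84,high_is_risk,10,1500,NA
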