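name,mean,median,sd,iqr,min,max,cv,ks_p
Age,65.0,68.0,16.6,22.0,19.0,94.0,0.26,0.0052
BMI,29.5,29.4,5.87,7.24,15.4,52.0,0.20,0.1075
Hb,13.4,13.5,1.82,2.40,7.80,17.9,0.14,0.8427
WBC,11.1,10.3,4.19,5.11,3.10,35.6,0.38,0.0002
RBC,4.57,4.59,0.65,0.87,2.56,6.50,0.14,0.9991
PLT,215,205,82.6,93.8,8.40,681,0.38,0.0097
UREA,41.5,36.3,21.3,22.1,7.50,147,0.51,0.0001
CREA,1.02,0.95,0.39,0.42,0.34,2.81,0.38,0.0001
GFR,84.1,78.0,40.6,55.8,9.00,259,0.48,0.0148
GLU,143,120,69.3,54.8,65.0,595,0.48,0.0001
Na+,138,139,3.67,4.00,125,152,0.03,0.0004
K+,4.30,4.26,0.53,0.57,2.66,6.34,0.12,0.0145
Cl-,101,102,4.28,5.00,84.0,114,0.04,0.0019
CK-MB mass,4.70,3.36,5.79,3.55,0.31,61.4,1.23,0.0001
hsTnT,123,45.7,232,107,3.00,2011,1.88,0.0001
D-dimer,11193,6475,11407,9914,97.0,54982,1.02,0.0001
aD-dimer,26.1,11.8,67.1,15.9,0.16,755,2.57,0.0001
INR,1.20,1.07,0.73,0.17,0.87,12.9,0.61,0.0001
aPTT,42.9,29.6,42.1,11.3,15.8,222,0.98,0.0001
CRP,40.7,22.5,50.0,42.1,0.67,296,1.23,0.0001
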