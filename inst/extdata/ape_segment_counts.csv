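variable,absence_seg1,presence_seg1,absence_seg2,presence_seg2,chi2_published,p_published
Age,792,171,177,0,36.98,0.0001
BMI,797,166,172,5,24.36,0.0001
Hb,792,171,177,0,36.98,0.0001
WBC,819,144,150,27,0.01,0.9203
RBC,792,171,177,0,36.98,0.0001
PLT,797,166,172,5,24.36,0.0001
UREA,827,136,142,35,3.75,0.0528
CREA,821,142,148,29,0.31,0.5777
GFR,823,140,146,31,1.04,0.3078
GLU,837,126,132,45,17.86,0.0001
Na+,792,171,177,0,36.98,0.0001
K+,792,171,177,0,36.98,0.0001
Cl-,792,171,177,0,36.98,0.0001
CK-MB mass,838,125,131,46,19.84,0.0001
hsTnT,846,117,123,54,39.53,0.0001
D-dimer,851,112,118,59,55.24,0.0001
aD-dimer,836,127,133,44,15.97,0.0001
INR,831,132,138,39,8.13,0.0044
aPTT,843,120,126,51,31.36,0.0001
CRP,853,110,116,61,62.25,0.0001
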