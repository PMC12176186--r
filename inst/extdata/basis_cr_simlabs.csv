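measure,lab,p_value,q_value
DTV,Simulated Lab 1,3.50e-03,3.50e-03
DTV,Simulated Lab 2,3.95e-03,4.93e-03
DTV,Simulated Lab 3,3.42e-05,3.42e-05
DTV,Simulated Lab 4,3.57e-04,3.57e-04
DTV,Simulated Lab 5,1.63e-03,1.63e-03
DTV,Fisher,2.12e-11,2.64e-11
AUC,Simulated Lab 1,3.52e-06,3.52e-06
AUC,Simulated Lab 2,1.85e-06,9.27e-06
AUC,Simulated Lab 3,4.32e-10,4.32e-10
AUC,Simulated Lab 4,1.08e-07,1.08e-07
AUC,Simulated Lab 5,3.35e-07,3.35e-07
AUC,Fisher,1.68e-28,8.40e-28
AUCMAX,Simulated Lab 1,9.97e-05,9.97e-05
AUCMAX,Simulated Lab 2,1.46e-04,2.43e-04
AUCMAX,Simulated Lab 3,1.81e-07,1.81e-07
AUCMAX,Simulated Lab 4,1.43e-05,1.43e-05
AUCMAX,Simulated Lab 5,1.41e-04,1.41e-04
AUCMAX,Fisher,1.97e-18,3.28e-18
TGI,Simulated Lab 1,2.11e-04,2.11e-04
TGI,Simulated Lab 2,4.04e-05,1.01e-04
TGI,Simulated Lab 3,1.81e-07,1.81e-07
TGI,Simulated Lab 4,1.43e-05,1.43e-05
TGI,Simulated Lab 5,1.41e-04,1.41e-04
TGI,Fisher,1.20e-18,3.00e-18
PFS,Simulated Lab 1,1.48e-01,1.48e-01
PFS,Simulated Lab 2,3.17e-02,3.17e-02
PFS,Simulated Lab 3,2.20e-03,2.20e-03
PFS,Simulated Lab 4,3.20e-02,3.20e-02
PFS,Simulated Lab 5,7.01e-02,7.01e-02
PFS,Fisher,1.17e-04,1.17e-04
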