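measure,lab,p_value,q_value
DTV,HCI-BCM,1.43e-01,2.21e-01
DTV,MDACC,1.63e-01,2.72e-01
DTV,PDMR,4.04e-01,7.78e-01
DTV,WUSTL,9.18e-01,9.18e-01
DTV,WIST,NA,NA
DTV,Fisher,3.02e-01,3.77e-01
AUC,HCI-BCM,7.13e-02,1.78e-01
AUC,MDACC,2.49e-01,3.05e-01
AUC,PDMR,6.85e-01,7.78e-01
AUC,WUSTL,3.50e-01,6.73e-01
AUC,WIST,NA,NA
AUC,Fisher,2.06e-01,3.44e-01
AUCMAX,HCI-BCM,1.77e-01,2.21e-01
AUCMAX,MDACC,3.05e-01,3.05e-01
AUCMAX,PDMR,5.21e-01,7.78e-01
AUCMAX,WUSTL,4.69e-01,6.73e-01
AUCMAX,WIST,3.60e-01,4.80e-01
AUCMAX,Fisher,3.81e-01,3.81e-01
TGI,HCI-BCM,6.75e-02,1.78e-01
TGI,MDACC,6.65e-02,1.66e-01
TGI,PDMR,7.51e-01,7.78e-01
TGI,WUSTL,5.38e-01,6.73e-01
TGI,WIST,NA,NA
TGI,Fisher,1.25e-01,3.44e-01
PFS,HCI-BCM,4.17e-01,4.17e-01
PFS,MDACC,2.84e-02,1.42e-01
PFS,PDMR,7.78e-01,7.78e-01
PFS,WUSTL,2.00e-01,6.73e-01
PFS,WIST,4.80e-01,4.80e-01
PFS,Fisher,1.70e-01,3.44e-01
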