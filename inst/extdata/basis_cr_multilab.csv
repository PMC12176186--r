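measure,lab,p_value,q_value
DTV,HCI-BCM,5.10e-04,5.10e-04
DTV,MDACC,6.50e-04,1.37e-03
DTV,PDMR,1.41e-08,3.53e-08
DTV,WUSTL,9.00e-05,1.50e-03
DTV,WIST,2.27e-03,2.33e-03
DTV,Fisher,2.38e-16,5.94e-16
AUC,HCI-BCM,3.90e-04,4.90e-04
AUC,MDACC,8.20e-04,1.37e-03
AUC,PDMR,7.46e-08,1.24e-07
AUC,WUSTL,6.10e-04,7.60e-03
AUC,WIST,1.30e-03,2.33e-03
AUC,Fisher,3.69e-15,6.11e-15
AUCMAX,HCI-BCM,1.50e-04,3.30e-04
AUCMAX,MDACC,6.30e-04,1.37e-03
AUCMAX,PDMR,4.57e-06,4.57e-06
AUCMAX,WUSTL,4.00e-05,1.00e-03
AUCMAX,WIST,1.62e-03,2.33e-03
AUCMAX,Fisher,5.25e-15,6.56e-15
TGI,HCI-BCM,2.15e-09,1.08e-08
TGI,MDACC,3.81e-03,3.81e-03
TGI,PDMR,1.06e-21,5.30e-21
TGI,WUSTL,2.72e-10,1.36e-09
TGI,WIST,4.04e-09,2.02e-08
TGI,Fisher,7.25e-44,3.62e-43
PFS,HCI-BCM,2.00e-04,3.30e-04
PFS,MDACC,1.84e-03,2.30e-04
PFS,PDMR,1.99e-06,2.48e-06
PFS,WUSTL,2.30e-03,2.30e-03
PFS,WIST,2.33e-03,2.33e-03
PFS,Fisher,4.67e-13,4.67e-13
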