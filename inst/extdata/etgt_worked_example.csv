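tumor_model,lab,group,mouse_id,day,volume
TM1,LabA,treated,M1,0,138.90
TM1,LabA,treated,M1,4,157.70
TM1,LabA,treated,M1,7,231.80
TM1,LabA,treated,M1,11,326.10
TM1,LabA,treated,M1,14,393.60
TM1,LabA,treated,M1,18,649.00
TM1,LabA,treated,M1,21,702.30
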