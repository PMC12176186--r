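replicate,id,aucmax,bootstrap_id,bootstrap_aucmax
Control01,0,156.60,2,107.44
Control02,1,95.73,3,210.90
Control03,2,107.44,0,156.60
Control04,3,210.90,3,210.90
Treated01,4,-60.25,7,-43.21
Treated02,5,-60.63,6,-48.60
Treated03,6,-48.60,4,-60.52
Treated04,7,-43.21,6,-48.60
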