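population,trait,environment,model,sigma2_mg,h2_mg,sigma2_pg,h2_pg
TMF2,VSG,E1,MX2-A-AD,631.67,95.95,10.32,1.57
TMF2,GLNM,E1,MX2-ADI-AD,5.32,89.03,0.11,1.78
TMF2,SPADS,E1,2MG-EA,29.99,99.43,NA,NA
TMF2,SPADM,E1,MX2-ADI-AD,100.8,92.78,0.00,0.00
TMF2,GLAD,E1,2MG-EA,652962.40,93.47,NA,NA
TMF2,GYP,E1,2MG-EA,707.77,99.99,NA,NA
TXF2,VSG,E1,MX2-ADI-AD,748.54,95.08,32.92,4.18
TXF2,GLNM,E1,MX2-ADI-AD,7.40,90.16,0.35,4.26
TXF2,SPADS,E2,2MG-EAD,47.85,99.55,NA,NA
TXF2,SPADM,E1,MX2-ADI-AD,152.44,94.92,NA,NA
TXF2,GLAD,E1,MX2-ADI-AD,447104.80,84.46,11312.13,2.14
TXF2,GYP,E1,2MG-A,560.88,96.17,NA,NA
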