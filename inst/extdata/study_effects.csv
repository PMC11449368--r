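population,trait,environment,model,da,db,ha,hb,i,jab,jba,l,d_poly,h_poly
TMF2,VSG,E1,MX2-A-AD,28.28,17.95,NA,NA,NA,NA,NA,NA,-18.34,42.74
TMF2,GLNM,E1,MX2-ADI-AD,4.62,2.36,-2.36,-3.34,2.36,-1.38,-0.10,3.13,-4.31,7.26
TMF2,SPADS,E1,2MG-EA,3.04,NA,NA,NA,NA,NA,NA,NA,NA,NA
TMF2,SPADM,E1,MX2-ADI-AD,16.74,7.25,-22.59,-19.35,16.74,4.79,-4.07,21.53,-6.83,63.27
TMF2,GLAD,E1,2MG-EA,876.17,NA,NA,NA,NA,NA,NA,NA,NA,NA
TMF2,GYP,E1,2MG-EA,3.17,NA,NA,NA,NA,NA,NA,NA,NA,NA
TXF2,VSG,E1,MX2-ADI-AD,29.65,4.62,-7.61,-4.95,5.24,13.73,1.90,29.46,-6.06,20.30
TXF2,GLNM,E1,MX2-ADI-AD,1.74,-1.07,-1.61,-2.11,2.69,1.65,2.77,1.81,2.50,6.45
TXF2,SPADS,E2,2MG-EAD,3.62,NA,NA,NA,NA,NA,NA,NA,NA,NA
TXF2,SPADM,E1,MX2-ADI-AD,-5.16,-16.78,-27.67,-18.72,22.94,20.99,23.66,16.94,37.86,73.71
TXF2,GLAD,E1,MX2-ADI-AD,440.14,5.00,-938.71,-935.77,505.68,425.93,-2.98,1176.73,1178.49,2109.62
TXF2,GYP,E1,2MG-A,26.56,-6.84,NA,NA,NA,NA,NA,NA,NA,NA
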