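population,trait,environment,p1_mean,p1_sd,p2_mean,p2_sd,f2_mean,f2_sd,cv,skewness,kurtosis
TMF2,VSG,E1,59.40,4.57,9.52,16.50,51.39,25.66,49.93,0.05,-0.88
TMF2,VSG,E2,69.26,8.91,6.06,5.25,46.82,25.86,55.24,-0.23,-0.71
TMF2,GLNM,E1,6.33,0.58,0.67,1.15,5.02,2.48,49.32,-0.12,-1.00
TMF2,GLNM,E2,6.67,0.58,0.67,0.58,4.36,2.56,58.68,-0.01,-0.66
TMF2,SPADS,E1,60.48,1.19,51.30,0.66,48.31,5.49,11.37,-0.13,0.26
TMF2,SPADS,E2,60.51,0.82,52.39,1.40,55.53,7.17,12.91,-0.62,0.76
TMF2,SPADM,E1,41.33,10.68,9.39,0.80,22.42,10.43,46.50,0.34,0.33
TMF2,SPADM,E2,42.64,2.55,10.33,4.10,20.05,13.05,65.12,0.93,-0.27
TMF2,GLAD,E1,2979.43,389.52,1153.23,135.83,2817.07,897.31,31.85,0.46,0.46
TMF2,GLAD,E2,3052.13,269.74,1406.26,13.91,3179.24,1269.91,39.94,0.55,-0.25
TMF2,GYP,E1,84.83,7.31,65.23,4.12,53.73,26.60,49.52,0.22,-0.40
TMF2,GYP,E2,85.13,3.68,64.31,4.42,63.87,38.41,60.13,0.54,-0.23
TXF2,VSG,E1,59.40,4.57,18.98,1.42,55.82,28.06,50.27,-0.25,-0.91
TXF2,VSG,E2,69.26,8.91,21.48,1.28,49.59,23.57,47.54,-0.73,-0.15
TXF2,GLNM,E1,6.33,0.58,1.67,0.58,5.23,2.86,54.75,-0.06,-0.84
TXF2,GLNM,E2,6.67,0.58,1.33,0.58,5.14,2.45,47.58,-0.62,-0.10
TXF2,SPADS,E1,60.48,1.19,41.48,3.37,45.01,7.89,17.53,0.07,-0.59
TXF2,SPADS,E2,60.51,0.82,42.86,3.14,49.67,6.93,13.96,-0.25,-0.01
TXF2,SPADM,E1,41.33,10.68,12.92,4.21,19.54,12.67,64.84,0.57,-0.98
TXF2,SPADM,E2,42.64,2.55,10.70,0.85,14.40,13.08,90.82,0.99,-0.31
TXF2,GLAD,E1,2979.43,389.52,1633.99,213.56,2767.59,726.59,26.25,0.33,0.52
TXF2,GLAD,E2,3052.13,269.74,1489.94,297.46,4160.24,1369.63,32.92,0.35,0.19
TXF2,GYP,E1,84.83,7.31,48.40,0.66,73.52,24.15,32.85,0.55,-0.05
TXF2,GYP,E2,85.13,3.68,46.94,0.69,57.08,30.26,53.01,0.11,-0.84
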