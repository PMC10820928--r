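substance_id,duplicate,lab_id,endpoint,plate,bmc_uM,inactive,at_lowest_conc,max_conc_uM
Aldicarb,1,LabA,Mortality@120,1,100,TRUE,FALSE,100
Aldicarb,1,LabA,Mortality@120,2,90.45,FALSE,FALSE,100
Aldicarb,1,LabA,Mortality@120,3,90.45,FALSE,FALSE,100
Aldicarb,1,LabB,Mortality@120,1,100,TRUE,FALSE,100
Aldicarb,1,LabB,Mortality@120,2,100,TRUE,FALSE,100
Aldicarb,1,LabB,Mortality@120,3,100,TRUE,FALSE,100
Aldicarb,1,LabC,Mortality@120,1,100,TRUE,FALSE,100
Aldicarb,1,LabC,Mortality@120,2,100,TRUE,FALSE,100
Aldicarb,1,LabC,Mortality@120,3,100,TRUE,FALSE,100
Aldicarb,1,LabA,MalformedAny+Mort@120,1,1.39,FALSE,TRUE,100
Aldicarb,1,LabA,MalformedAny+Mort@120,2,0.53,FALSE,FALSE,100
Aldicarb,1,LabA,MalformedAny+Mort@120,3,1.44,FALSE,FALSE,100
Aldicarb,1,LabB,MalformedAny+Mort@120,1,1.32,FALSE,FALSE,100
Aldicarb,1,LabB,MalformedAny+Mort@120,2,1.42,FALSE,FALSE,100
Aldicarb,1,LabB,MalformedAny+Mort@120,3,2.24,FALSE,FALSE,100
Aldicarb,1,LabC,MalformedAny+Mort@120,1,2.09,FALSE,FALSE,100
Aldicarb,1,LabC,MalformedAny+Mort@120,2,1.31,FALSE,FALSE,100
Aldicarb,1,LabC,MalformedAny+Mort@120,3,2.58,FALSE,FALSE,100
Aldicarb,2,LabA,Mortality@120,1,90.45,FALSE,FALSE,100
Aldicarb,2,LabA,Mortality@120,2,86.41,FALSE,FALSE,100
Aldicarb,2,LabA,Mortality@120,3,100,TRUE,FALSE,100
Aldicarb,2,LabB,Mortality@120,1,100,TRUE,FALSE,100
Aldicarb,2,LabB,Mortality@120,2,100,TRUE,FALSE,100
Aldicarb,2,LabB,Mortality@120,3,100,TRUE,FALSE,100
Aldicarb,2,LabC,Mortality@120,1,100,TRUE,FALSE,100
Aldicarb,2,LabC,Mortality@120,2,100,TRUE,FALSE,100
Aldicarb,2,LabC,Mortality@120,3,100,TRUE,FALSE,100
Aldicarb,2,LabA,MalformedAny+Mort@120,1,0.81,FALSE,FALSE,100
Aldicarb,2,LabA,MalformedAny+Mort@120,2,0.81,FALSE,FALSE,100
Aldicarb,2,LabA,MalformedAny+Mort@120,3,0.58,FALSE,FALSE,100
Aldicarb,2,LabB,MalformedAny+Mort@120,1,2.52,FALSE,FALSE,100
Aldicarb,2,LabB,MalformedAny+Mort@120,2,2.52,FALSE,FALSE,100
Aldicarb,2,LabB,MalformedAny+Mort@120,3,3.58,FALSE,FALSE,100
Aldicarb,2,LabC,MalformedAny+Mort@120,1,2.32,FALSE,FALSE,100
Aldicarb,2,LabC,MalformedAny+Mort@120,2,1.57,FALSE,FALSE,100
Aldicarb,2,LabC,MalformedAny+Mort@120,3,1.75,FALSE,FALSE,100
Bisphenol A,1,LabA,Mortality@120,1,40.54,FALSE,FALSE,100
Bisphenol A,1,LabA,Mortality@120,2,40.54,FALSE,FALSE,100
Bisphenol A,1,LabA,Mortality@120,3,40.54,FALSE,FALSE,100
Bisphenol A,1,LabB,Mortality@120,1,61.05,FALSE,FALSE,100
Bisphenol A,1,LabB,Mortality@120,2,79.16,FALSE,FALSE,100
Bisphenol A,1,LabB,Mortality@120,3,55.75,FALSE,FALSE,100
Bisphenol A,1,LabC,Mortality@120,1,38.18,FALSE,FALSE,100
Bisphenol A,1,LabC,Mortality@120,2,38.18,FALSE,FALSE,100
Bisphenol A,1,LabC,Mortality@120,3,38.18,FALSE,FALSE,100
Bisphenol A,1,LabA,MalformedAny+Mort@120,1,13.90,FALSE,FALSE,100
Bisphenol A,1,LabA,MalformedAny+Mort@120,2,14.37,FALSE,FALSE,100
Bisphenol A,1,LabA,MalformedAny+Mort@120,3,13.90,FALSE,FALSE,100
Bisphenol A,1,LabB,MalformedAny+Mort@120,1,32.86,FALSE,FALSE,100
Bisphenol A,1,LabB,MalformedAny+Mort@120,2,40.29,FALSE,FALSE,100
Bisphenol A,1,LabB,MalformedAny+Mort@120,3,39.49,FALSE,FALSE,100
Bisphenol A,1,LabC,MalformedAny+Mort@120,1,45.73,FALSE,FALSE,100
Bisphenol A,1,LabC,MalformedAny+Mort@120,2,18.19,FALSE,FALSE,100
Bisphenol A,1,LabC,MalformedAny+Mort@120,3,19.24,FALSE,FALSE,100
Bisphenol A,2,LabA,Mortality@120,1,40.54,FALSE,FALSE,100
Bisphenol A,2,LabA,Mortality@120,2,40.54,FALSE,FALSE,100
Bisphenol A,2,LabA,Mortality@120,3,40.54,FALSE,FALSE,100
Bisphenol A,2,LabB,Mortality@120,1,55.75,FALSE,FALSE,100
Bisphenol A,2,LabB,Mortality@120,2,58.52,FALSE,FALSE,100
Bisphenol A,2,LabB,Mortality@120,3,46.38,FALSE,FALSE,100
Bisphenol A,2,LabC,Mortality@120,1,38.18,FALSE,FALSE,100
Bisphenol A,2,LabC,Mortality@120,2,38.18,FALSE,FALSE,100
Bisphenol A,2,LabC,Mortality@120,3,17.47,FALSE,FALSE,100
Bisphenol A,2,LabA,MalformedAny+Mort@120,1,13.90,FALSE,FALSE,100
Bisphenol A,2,LabA,MalformedAny+Mort@120,2,13.90,FALSE,FALSE,100
Bisphenol A,2,LabA,MalformedAny+Mort@120,3,8.10,FALSE,FALSE,100
Bisphenol A,2,LabB,MalformedAny+Mort@120,1,39.49,FALSE,FALSE,100
Bisphenol A,2,LabB,MalformedAny+Mort@120,2,39.49,FALSE,FALSE,100
Bisphenol A,2,LabB,MalformedAny+Mort@120,3,39.49,FALSE,FALSE,100
Bisphenol A,2,LabC,MalformedAny+Mort@120,1,16.45,FALSE,FALSE,100
Bisphenol A,2,LabC,MalformedAny+Mort@120,2,14.48,FALSE,FALSE,100
Bisphenol A,2,LabC,MalformedAny+Mort@120,3,16.45,FALSE,FALSE,100
Valproic acid,1,LabA,Mortality@120,1,100,TRUE,FALSE,100
Valproic acid,1,LabA,Mortality@120,2,100,TRUE,FALSE,100
Valproic acid,1,LabA,Mortality@120,3,100,TRUE,FALSE,100
Valproic acid,1,LabB,Mortality@120,1,100,TRUE,FALSE,100
Valproic acid,1,LabB,Mortality@120,2,100,TRUE,FALSE,100
Valproic acid,1,LabB,Mortality@120,3,100,TRUE,FALSE,100
Valproic acid,1,LabC,Mortality@120,1,11.47,FALSE,FALSE,100
Valproic acid,1,LabC,Mortality@120,2,11.47,FALSE,FALSE,100
Valproic acid,1,LabC,Mortality@120,3,3.63,FALSE,FALSE,100
Valproic acid,1,LabA,MalformedAny+Mort@120,1,46.65,FALSE,FALSE,100
Valproic acid,1,LabA,MalformedAny+Mort@120,2,58.17,FALSE,FALSE,100
Valproic acid,1,LabA,MalformedAny+Mort@120,3,58.17,FALSE,FALSE,100
Valproic acid,1,LabB,MalformedAny+Mort@120,1,100,TRUE,FALSE,100
Valproic acid,1,LabB,MalformedAny+Mort@120,2,100,TRUE,FALSE,100
Valproic acid,1,LabB,MalformedAny+Mort@120,3,87.87,FALSE,FALSE,100
Valproic acid,1,LabC,MalformedAny+Mort@120,1,0.98,FALSE,FALSE,100
Valproic acid,1,LabC,MalformedAny+Mort@120,2,4.12,FALSE,FALSE,100
Valproic acid,1,LabC,MalformedAny+Mort@120,3,4.12,FALSE,FALSE,100
Valproic acid,2,LabA,Mortality@120,1,100,TRUE,FALSE,100
Valproic acid,2,LabA,Mortality@120,2,100,TRUE,FALSE,100
Valproic acid,2,LabA,Mortality@120,3,100,TRUE,FALSE,100
Valproic acid,2,LabB,Mortality@120,1,100,TRUE,FALSE,100
Valproic acid,2,LabB,Mortality@120,2,100,TRUE,FALSE,100
Valproic acid,2,LabB,Mortality@120,3,100,TRUE,FALSE,100
Valproic acid,2,LabC,Mortality@120,1,11.47,FALSE,FALSE,100
Valproic acid,2,LabC,Mortality@120,2,38.18,FALSE,FALSE,100
Valproic acid,2,LabC,Mortality@120,3,6.54,FALSE,FALSE,100
Valproic acid,2,LabA,MalformedAny+Mort@120,1,100,TRUE,FALSE,100
Valproic acid,2,LabA,MalformedAny+Mort@120,2,100,TRUE,FALSE,100
Valproic acid,2,LabA,MalformedAny+Mort@120,3,100,TRUE,FALSE,100
Valproic acid,2,LabB,MalformedAny+Mort@120,1,100,TRUE,FALSE,100
Valproic acid,2,LabB,MalformedAny+Mort@120,2,100,TRUE,FALSE,100
Valproic acid,2,LabB,MalformedAny+Mort@120,3,100,TRUE,FALSE,100
Valproic acid,2,LabC,MalformedAny+Mort@120,1,20.94,FALSE,FALSE,100
Valproic acid,2,LabC,MalformedAny+Mort@120,2,1.75,FALSE,FALSE,100
Valproic acid,2,LabC,MalformedAny+Mort@120,3,4.12,FALSE,FALSE,100
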