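chemical,analyte,metric,value,lower,upper,unit
BPA,parent,cmax,0.43,0.3,0.7,nM
BPA,glucuronide,cmax,286,173,386,nM
BPS,parent,cmax,8.79,6.07,11.79,nM
BPS,glucuronide,cmax,10.53,7.77,14.2,nM
BPA,parent,tmax,1.6,0.5,2.2,h
BPA,glucuronide,tmax,1.2,0.8,2.2,h
BPS,parent,tmax,0.5,0.25,0.5,h
BPS,glucuronide,tmax,1.0,1.0,1.0,h
BPA,parent,auc,2.5,1.4,5.7,nM*h
BPA,glucuronide,auc,680,571,1210,nM*h
BPS,parent,auc,40,NA,NA,nM*h
BPS,glucuronide,auc,78.7,54,103,nM*h
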