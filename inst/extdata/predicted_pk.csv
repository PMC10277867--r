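compound,dose_mg,auc,cmax,tmax
ertugliflozin,15,1238.5,263.08,1
ertugliflozin,1,75.4,18.82,1
ertugliflozin,5,393.82,95.5,1.04
ertugliflozin,25,2485.6,437.61,1.16
empagliflozin,1,141.73,16.19,1.25
empagliflozin,10,1493.5,147.55,1.3
empagliflozin,25,2919.5,317.5,1.78
empagliflozin,100,9507.7,1201.4,2.12
henagliflozin,2.5,395.1,52.1,0.96
henagliflozin,5,766.09,106.92,0.96
henagliflozin,10,1413.4,205.1,1.16
henagliflozin,25,3642,457.07,1.1
henagliflozin,50,7449.5,964.07,1.1
henagliflozin,100,13930,1732.5,1.6
henagliflozin,200,28630,3305.1,1.68
sotagliflozin,200,475.36,115.82,0.72
sotagliflozin,400,928.08,195.54,0.72
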