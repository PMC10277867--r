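compound,dose_mg,auc,cmax,tmax,population_tag
ertugliflozin,15,1291.7,266.17,1,non-Asian
ertugliflozin,1,68.09,17.9,1,Asian
ertugliflozin,5,433.79,79.7,1.02,Asian
ertugliflozin,25,2151.4,432,1.25,Asian
empagliflozin,1,129.01,14.63,1.25,Asian
empagliflozin,10,1286.5,148.83,1.5,Asian
empagliflozin,25,2843.7,284.5,2,Asian
empagliflozin,100,10590,1192.1,2.5,Asian
henagliflozin,2.5,408,54.8,1.5,Asian
henagliflozin,5,796.69,117.37,1.5,Asian
henagliflozin,10,1415.6,161.7,1.75,Asian
henagliflozin,25,3384.1,406,2,Asian
henagliflozin,50,7671.8,941.7,1.5,Asian
henagliflozin,100,13440,1460,2,Asian
henagliflozin,200,28480,3140.5,1.5,Asian
sotagliflozin,200,631.14,90.9,1,Asian
sotagliflozin,400,1129.8,151,1,Asian
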