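site,compound,dose_mg,max_ratio_pct
duodenum,ertugliflozin,5,0.14
duodenum,ertugliflozin,10,0.43
duodenum,empagliflozin,10,2.33
duodenum,empagliflozin,25,3.90
duodenum,henagliflozin,5,0.07
duodenum,henagliflozin,10,0.11
duodenum,sotagliflozin,200,89.54
duodenum,sotagliflozin,400,94.47
jejunum1,ertugliflozin,5,0.09
jejunum1,ertugliflozin,10,0.26
jejunum1,empagliflozin,10,1.74
jejunum1,empagliflozin,25,3.22
jejunum1,henagliflozin,5,0.04
jejunum1,henagliflozin,10,0.07
jejunum1,sotagliflozin,200,81.41
jejunum1,sotagliflozin,400,89.75
S3,ertugliflozin,5,0.09
S3,ertugliflozin,10,0.26
S3,empagliflozin,10,0.89
S3,empagliflozin,25,1.91
S3,henagliflozin,5,0.04
S3,henagliflozin,10,0.08
S3,sotagliflozin,200,6.66
S3,sotagliflozin,400,13.05
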