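compartment,length_cm,radius_cm,volume_ml,transit_h_default,sitt_fraction
stomach,NA,NA,50,0.25,NA
duodenum,14.1,1.6,113.4,NA,0.0788
jejunum1,58.4,1.53,429.5,NA,0.2879
jejunum2,58.4,1.45,385.7,NA,0.2242
ileum1,58.4,1.36,339.3,NA,0.1758
ileum2,58.4,1.27,295.9,NA,0.1273
ileum3,42.8,1.19,190.4,NA,0.106
caecum,13.75,3.39,52,4.5,NA
asc_colon,28.5,2.41,56,8.5,NA
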