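tissue,volume_l,flow_frac_co
lung,0.53,1.0
heart,0.33,0.04
brain,1.45,0.114
muscle,29.0,0.17
adipose,13.5,0.05
skin,3.4,0.05
bone_rest,9.5,0.1505
spleen,0.19,0.02
gut,1.2,0.15
liver,1.8,0.065
kidney,0.31,0.19
reproductive,0.05,0.0005
arterial,1.7,NA
venous,3.9,NA
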