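tissue,f_ew,f_iw,f_nl,f_npl,ra_alb
adipose,0.135,0.017,0.79,0.002,0.049
bone_rest,0.1,0.346,0.074,0.0011,0.1
brain,0.162,0.62,0.051,0.0565,0.048
gut,0.282,0.475,0.049,0.0163,0.158
heart,0.32,0.456,0.014,0.0111,0.157
kidney,0.273,0.483,0.012,0.0242,0.13
liver,0.161,0.573,0.014,0.024,0.086
lung,0.336,0.446,0.022,0.0128,0.212
muscle,0.118,0.63,0.01,0.0072,0.064
skin,0.382,0.291,0.06,0.0044,0.277
spleen,0.207,0.579,0.0077,0.0113,0.097
reproductive,0.28,0.595,0.0048,0.0029,0.11
plasma,0.945,0,0.0023,0.0013,1
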