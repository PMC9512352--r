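# Tissue parameter presets.
# C1_tumor: RCR Category-1 rapidly proliferating head-and-neck/lung tumor.
# K in Gy/day, T_delay in calendar days, repair_half_time in hours.
name,alpha_beta,K,T_delay,repair_half_time,class
C1_tumor,10,0.9,28,2,tumor
generic_oar,3,0,0,2,oar
spinal_cord,2,0,0,2,oar
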