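role,label,absorbance,venom_mass_mg,time_min
blank,PBS_blank,0.05,NA,NA
positive,triton_PC,1.25,NA,NA
sample,triton_PC,1.25,NA,NA
sample,venom_1ug,0.12,NA,NA
sample,venom_30ug,0.53,NA,NA
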