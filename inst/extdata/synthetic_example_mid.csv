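sample_id,compound,isotopologue,value,value_type,condition,oxygen,tracer,acetate_spike_uM,replicate
hypoxia_both_rep1,palmitate,0,51014,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,1,8642,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,2,1869,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,3,251,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,4,4139,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,5,496,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,6,8250,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,7,870,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,8,9996,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,9,916,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,10,7845,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,11,520,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,12,3814,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,13,167,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,14,1064,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,15,18,intensity,hypoxia_both,hypoxia,both,,1
hypoxia_both_rep1,palmitate,16,129,intensity,hypoxia_both,hypoxia,both,,1
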