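form_id,t_melt_C,dH_kJ_per_mol
VPZ-RES,93,38
VPZ-CAT,103.9,53
VPZ-GAL,130,57
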