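scenario,community_1_eu_ca,community_2_swa_af_sa,community_3_esa_na_oa,units
baseline,8700,16600,27100,Gg a-1
import_substitution,210,50,80,Gg a-1
export_transfer,750,450,470,Gg a-1
fertilizer_overuse,550,1400,2500,Gg a-1
deep_placement,1700,3800,6500,Gg a-1
enhanced_efficiency,1600,3700,6300,Gg a-1
manure_moderate,1400,1600,2400,Gg a-1
manure_drastic,2700,3200,4800,Gg a-1
mtfr,2800,7100,15200,Gg a-1
food_waste,2300,4500,7800,Gg a-1
beef_cut20,260,380,570,Gg a-1
beef_cut50,650,940,1400,Gg a-1
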