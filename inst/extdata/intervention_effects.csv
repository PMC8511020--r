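name,effect,effect_lo,effect_hi,unit,source
micronutrient_supplementation,0.1810,0.1257,0.3234,WAZ sigma per treated child,after Bhutta et al. 2008 meta-analysis
complementary_foods,0.3369,0.2310,0.7351,WAZ sigma per treated child,after Bhutta et al. 2008 meta-analysis
nutrition_education,0.3369,0.2056,0.9330,WAZ sigma per treated child,after Bhutta et al. 2008 meta-analysis
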