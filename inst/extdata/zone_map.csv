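"disease","zones"
"NPC","midbrain"
"AT","vermis/fastigial nucleus;frontoparietal cortex"
"AOA1/2","vermis/fastigial nucleus;frontoparietal cortex"
"GD3","pons"
"TS","midbrain"
"Wernicke encephalopathy","pons;medulla oblongata"
"Huntington chorea","basal ganglia;frontoparietal cortex"
"MS","pons;midbrain"
"Parkinsonian syndromes","basal ganglia"
"PSP","midbrain;basal ganglia"
"tumor",""
"infarction/hemorrhage","pons;medulla oblongata"
"inflammatory encephalitis","frontoparietal cortex"
"cerebellar syndromes","flocculus/paraflocculus;vermis/fastigial nucleus;nodulus/uvula"
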