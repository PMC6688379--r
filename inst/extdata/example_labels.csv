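"patient_id","true_disease","true_zones","zones_evaluable"
"example-1","NPC","midbrain",TRUE
"example-2","Wernicke encephalopathy","pons;medulla oblongata",TRUE
"example-3","PSP","midbrain;basal ganglia",TRUE
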