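"patient_id","ataxia","dysarthria","dysphagia","paresis","resting tremor","intention tremor","rigidity","bradykinesia","chorea","dystonia","cognitive decline","psychiatric symptoms","epileptic seizures","polyneuropathy","telangiectasia","splenomegaly","confusion","falls","sensory deficits","headache","acute onset","vertical saccade palsy","horizontal saccade palsy","vertical supranuclear gaze palsy","horizontal supranuclear gaze palsy","internuclear ophthalmoplegia, aged < 60 years","internuclear ophthalmoplegia, aged >= 60 years","oculomotor apraxia","slowed vertical saccades","slowed horizontal saccades","hypometric saccades","hypermetric saccades","saccadic smooth pursuit","gaze-evoked nystagmus","downbeat nystagmus","upbeat nystagmus","rebound nystagmus","spontaneous nystagmus","fixation nystagmus","head-shaking nystagmus","positional nystagmus","periodic alternating nystagmus","convergence-retraction nystagmus","square wave jerks","macrosaccadic oscillations","saccadic intrusions","ocular flutter","opsoclonus","convergence impairment","ptosis","diplopia","skew deviation","ocular tilt reaction","impaired VOR suppression","bilateral vestibulopathy","head impulse test positive","optokinetic nystagmus impairment","vertical gaze-holding deficit","lid retraction","reduced blink rate"
"example-1","Yes","0","0","No","No","0","0","0","No","0","0","Yes","0","0","No","Yes","0","0","0","0","0","Yes","0","Yes","0","0","0","0","Yes","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0"
"example-2","Yes","0","0","0","No","0","0","0","No","0","0","0","0","0","0","0","Yes","0","0","0","0","No","0","0","0","0","0","0","0","0","0","0","0","Yes","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","Yes","0","0","0","Yes","0","0","0","0","0"
"example-3","0","0","0","0","No","0","Yes","Yes","No","0","0","0","0","0","No","0","0","Yes","0","0","0","0","0","Yes","0","0","0","0","Yes","0","0","0","0","0","0","0","0","0","0","0","0","0","0","Yes","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0","0"
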