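# entity_kind: DISEASE
symptom	group	NPC	AT	AOA1/2	GD3	TS	Wernicke encephalopathy	Huntington chorea	MS	Parkinsonian syndromes	PSP	tumor	infarction/hemorrhage	inflammatory encephalitis	cerebellar syndromes
ataxia	GENERAL	Y	Y	Y	Y	Y	Y	N	Y	N	N	N	N	N	Y
dysarthria	GENERAL	Y	Y	N	Y	Y	N	N	N	N	N	N	Y	N	Y
dysphagia	GENERAL	Y	N	N	N	N	N	N	N	N	N	N	N	N	N
paresis	GENERAL	OTTD	N	N	OTTD	Y	N	N	Y	N	N	Y	Y	N	N
resting tremor	GENERAL	N	N	N	N	N	N	N	N	HR	UL	N	N	N	N
intention tremor	GENERAL	N	N	N	N	N	N	N	N	N	N	N	N	N	Y
rigidity	GENERAL	N	N	N	N	N	N	N	N	Y	Y	N	N	N	N
bradykinesia	GENERAL	N	N	N	N	N	N	N	N	Y	Y	N	N	N	N
chorea	GENERAL	N	Y	Y	N	N	N	HR	N	N	N	N	N	N	N
dystonia	GENERAL	Y	N	Y	N	N	N	Y	N	N	N	N	N	N	N
cognitive decline	GENERAL	Y	N	N	N	N	N	Y	N	N	Y	Y	N	N	N
psychiatric symptoms	GENERAL	Y	N	N	N	Y	N	Y	N	N	N	N	N	Y	N
epileptic seizures	GENERAL	N	N	N	Y	Y	N	N	N	N	N	Y	N	Y	N
polyneuropathy	GENERAL	N	Y	HR	N	N	N	N	N	N	N	N	N	N	N
telangiectasia	GENERAL	N	HR	N	N	N	N	N	N	N	N	N	N	N	N
splenomegaly	GENERAL	Y	N	N	Y	N	N	N	N	N	N	N	N	N	N
confusion	GENERAL	N	N	N	N	N	HR	N	N	N	N	N	N	Y	N
falls	GENERAL	N	N	N	N	N	N	N	N	N	HR	N	N	N	N
sensory deficits	GENERAL	N	N	N	N	N	N	N	Y	N	N	N	Y	N	N
headache	GENERAL	N	N	N	N	N	N	N	N	N	N	HR	N	Y	N
acute onset	GENERAL	N	N	N	N	N	N	N	N	N	N	N	HR	N	N
vertical saccade palsy	OCULOMOTOR	HR	N	N	N	HR	N	N	N	N	N	N	N	N	N
horizontal saccade palsy	OCULOMOTOR	N	N	N	HR	N	N	N	N	N	N	N	N	N	N
vertical supranuclear gaze palsy	OCULOMOTOR	HR	N	N	N	N	N	N	N	N	Y	N	N	N	N
horizontal supranuclear gaze palsy	OCULOMOTOR	N	N	N	HR	N	Y	N	N	N	N	N	N	N	N
internuclear ophthalmoplegia, aged < 60 years	OCULOMOTOR	N	N	N	N	N	N	N	HR	N	N	N	N	N	N
internuclear ophthalmoplegia, aged >= 60 years	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	N
oculomotor apraxia	OCULOMOTOR	N	HR	HR	N	N	N	N	N	N	N	N	N	N	N
slowed vertical saccades	OCULOMOTOR	Y	N	N	N	Y	N	N	N	N	HR	N	N	N	N
slowed horizontal saccades	OCULOMOTOR	N	N	N	Y	N	N	Y	N	N	N	N	N	N	N
hypometric saccades	OCULOMOTOR	N	Y	Y	N	N	N	Y	N	Y	N	N	N	N	N
hypermetric saccades	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	Y
saccadic smooth pursuit	OCULOMOTOR	N	N	Y	N	N	N	N	N	N	N	N	N	N	Y
gaze-evoked nystagmus	OCULOMOTOR	N	N	N	N	N	Y	N	Y	N	N	N	N	N	Y
downbeat nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	HR
upbeat nystagmus	OCULOMOTOR	N	N	N	N	N	Y	N	N	N	N	N	N	N	N
rebound nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	HR
spontaneous nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	Y	N	N	N	Y	N	N
fixation nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	Y	N
head-shaking nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	N
positional nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	N
periodic alternating nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	N
convergence-retraction nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	N
square wave jerks	OCULOMOTOR	N	N	N	N	N	N	N	N	Y	Y	N	N	N	N
macrosaccadic oscillations	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	N
saccadic intrusions	OCULOMOTOR	N	N	N	N	N	N	Y	N	N	N	N	N	N	N
ocular flutter	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	Y	N
opsoclonus	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	HR	N
convergence impairment	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	N
ptosis	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	N
diplopia	OCULOMOTOR	N	N	N	N	N	Y	N	Y	N	N	Y	N	N	N
skew deviation	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	Y	N	N
ocular tilt reaction	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	Y	N	N
impaired VOR suppression	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	N	N	N	Y
bilateral vestibulopathy	OCULOMOTOR	N	N	N	N	N	Y	N	N	N	N	N	N	N	Y
head impulse test positive	OCULOMOTOR	N	Y	N	N	N	N	N	N	N	N	N	N	N	Y
optokinetic nystagmus impairment	OCULOMOTOR	N	N	N	N	N	Y	N	Y	N	N	N	N	N	N
vertical gaze-holding deficit	OCULOMOTOR	N	N	N	N	N	N	N	N	N	N	Y	N	N	N
lid retraction	OCULOMOTOR	N	N	N	N	N	N	N	N	N	Y	N	N	N	N
reduced blink rate	OCULOMOTOR	N	N	N	N	N	N	N	N	Y	Y	N	N	N	N
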