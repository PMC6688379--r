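# entity_kind: BRAIN_ZONE
symptom	group	midbrain	pons	medulla oblongata	basal ganglia	frontoparietal cortex	flocculus/paraflocculus	vermis/fastigial nucleus	nodulus/uvula
ataxia	GENERAL	N	N	N	N	N	N	R	N
dysarthria	GENERAL	N	R	R	N	N	N	N	N
dysphagia	GENERAL	N	N	R	N	N	N	N	N
paresis	GENERAL	N	R	N	N	N	N	N	N
resting tremor	GENERAL	N	N	N	HR	N	N	N	N
intention tremor	GENERAL	N	N	N	N	N	N	R	N
rigidity	GENERAL	N	N	N	R	N	N	N	N
bradykinesia	GENERAL	N	N	N	R	N	N	N	N
chorea	GENERAL	N	N	N	HR	N	N	N	N
dystonia	GENERAL	N	N	N	R	N	N	N	N
cognitive decline	GENERAL	N	N	N	N	R	N	N	N
psychiatric symptoms	GENERAL	N	N	N	N	R	N	N	N
epileptic seizures	GENERAL	N	N	N	N	R	N	N	N
polyneuropathy	GENERAL	N	N	N	N	N	N	N	N
telangiectasia	GENERAL	N	N	N	N	N	N	N	N
splenomegaly	GENERAL	N	N	N	N	N	N	N	N
confusion	GENERAL	N	N	N	N	R	N	N	N
falls	GENERAL	N	N	N	N	N	N	N	N
sensory deficits	GENERAL	N	N	N	N	N	N	N	N
headache	GENERAL	N	N	N	N	R	N	N	N
acute onset	GENERAL	N	N	N	N	N	N	N	N
vertical saccade palsy	OCULOMOTOR	HR	N	N	N	N	N	N	N
horizontal saccade palsy	OCULOMOTOR	N	HR	N	N	N	N	N	N
vertical supranuclear gaze palsy	OCULOMOTOR	HR	N	N	N	N	N	N	N
horizontal supranuclear gaze palsy	OCULOMOTOR	N	HR	N	N	N	N	N	N
internuclear ophthalmoplegia, aged < 60 years	OCULOMOTOR	R	R	N	N	N	N	N	N
internuclear ophthalmoplegia, aged >= 60 years	OCULOMOTOR	R	R	N	N	N	N	N	N
oculomotor apraxia	OCULOMOTOR	N	N	N	N	HR	N	N	N
slowed vertical saccades	OCULOMOTOR	R	N	N	N	N	N	N	N
slowed horizontal saccades	OCULOMOTOR	N	R	N	N	N	N	N	N
hypometric saccades	OCULOMOTOR	N	N	N	R	N	N	R	N
hypermetric saccades	OCULOMOTOR	N	N	N	N	N	N	HR	N
saccadic smooth pursuit	OCULOMOTOR	N	N	N	N	N	R	R	N
gaze-evoked nystagmus	OCULOMOTOR	N	N	N	N	N	R	N	N
downbeat nystagmus	OCULOMOTOR	N	N	N	N	N	HR	N	N
upbeat nystagmus	OCULOMOTOR	R	N	HR	N	N	N	N	N
rebound nystagmus	OCULOMOTOR	N	N	N	N	N	R	N	N
spontaneous nystagmus	OCULOMOTOR	N	R	R	N	N	N	N	R
fixation nystagmus	OCULOMOTOR	N	N	N	N	N	R	N	N
head-shaking nystagmus	OCULOMOTOR	N	N	R	N	N	N	N	R
positional nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	HR
periodic alternating nystagmus	OCULOMOTOR	N	N	N	N	N	N	N	HR
convergence-retraction nystagmus	OCULOMOTOR	HR	N	N	N	N	N	N	N
square wave jerks	OCULOMOTOR	N	N	N	R	N	N	N	N
macrosaccadic oscillations	OCULOMOTOR	N	N	N	N	N	N	R	N
saccadic intrusions	OCULOMOTOR	N	N	N	N	R	N	N	N
ocular flutter	OCULOMOTOR	N	N	N	N	N	N	N	N
opsoclonus	OCULOMOTOR	N	N	N	N	N	N	N	N
convergence impairment	OCULOMOTOR	R	N	N	N	N	N	N	N
ptosis	OCULOMOTOR	R	N	N	N	N	N	N	N
diplopia	OCULOMOTOR	N	R	N	N	N	N	N	N
skew deviation	OCULOMOTOR	R	R	R	N	N	N	N	N
ocular tilt reaction	OCULOMOTOR	N	R	HR	N	N	N	N	N
impaired VOR suppression	OCULOMOTOR	N	N	N	N	N	HR	N	N
bilateral vestibulopathy	OCULOMOTOR	N	N	N	N	N	N	N	N
head impulse test positive	OCULOMOTOR	N	N	N	N	N	N	N	N
optokinetic nystagmus impairment	OCULOMOTOR	N	N	N	N	N	R	N	N
vertical gaze-holding deficit	OCULOMOTOR	R	N	N	N	N	N	N	N
lid retraction	OCULOMOTOR	R	N	N	N	N	N	N	N
reduced blink rate	OCULOMOTOR	N	N	N	R	N	N	N	N
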