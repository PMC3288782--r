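surface	cui	concept	semtypes
aprazolam	C0002333	Alprazolam	orch,phsu
alprazolam	C0002333	Alprazolam	orch,phsu
fluvoxamine	C0085228	Fluvoxamine	orch,phsu
fluoxetine	C0016365	Fluoxetine	orch,phsu
sertraline	C0074393	Sertraline	orch,phsu
paroxetine	C0070122	Paroxetine	orch,phsu
venlafaxine	C0078569	Venlafaxine	orch,phsu
triamterene	C0040869	Triamterene	orch,phsu
metformin	C0025598	Metformin	orch,phsu
amiloride	C0002658	Amiloride	orch,phsu
dofetilide	C0113340	Dofetilide	orch,phsu
digoxin	C0012265	Digoxin	orch,phsu
diltiazem	C0012373	Diltiazem	orch,phsu
verapamil	C0042523	Verapamil	orch,phsu
midazolam	C0026056	Midazolam	orch,phsu
triazolam	C0040838	Triazolam	orch,phsu
lorazepam	C0024002	Lorazepam	orch,phsu
diazepam	C0012010	Diazepam	orch,phsu
cimetidine	C0008783	Cimetidine	orch,phsu
ranitidine	C0034665	Ranitidine	orch,phsu
omeprazole	C0028978	Omeprazole	orch,phsu
trandolapril	C0077647	Trandolapril	orch,phsu
enalapril	C0014025	Enalapril	orch,phsu
lisinopril	C0065374	Lisinopril	orch,phsu
losartan	C0126174	Losartan	orch,phsu
propranolol	C0033497	Propranolol	orch,phsu
atenolol	C0004147	Atenolol	orch,phsu
acitretin	C0050937	Acitretin	orch,phsu
naloxone	C0027358	Naloxone	orch,phsu
aspirin	C0004057	Aspirin	orch,phsu
warfarin	C0043031	Warfarin	orch,phsu
ibuprofen	C0020740	Ibuprofen	orch,phsu
celecoxib	C0538927	Celecoxib	orch,phsu
furosemide	C0016860	Furosemide	orch,phsu
hydrochlorothiazide	C0020261	Hydrochlorothiazide	orch,phsu
simvastatin	C0074554	Simvastatin	orch,phsu
atorvastatin	C0286651	Atorvastatin	orch,phsu
nifedipine	C0028066	Nifedipine	orch,phsu
amlodipine	C0051696	Amlodipine	orch,phsu
ketoconazole	C0022625	Ketoconazole	orch,phsu
erythromycin	C0014806	Erythromycin	orch,antb,phsu
clarithromycin	C0055856	Clarithromycin	orch,antb,phsu
ciprofloxacin	C0008809	Ciprofloxacin	orch,antb,phsu
amoxicillin	C0002645	Amoxicillin	orch,antb,phsu
doxycycline	C0013090	Doxycycline	orch,antb,phsu
rifampicin	C0035608	Rifampicin	orch,antb,phsu
theophylline	C0039771	Theophylline	orch,phsu
lithium	C0023870	Lithium	orch,phsu
quinidine	C0034414	Quinidine	orch,phsu
amiodarone	C0002598	Amiodarone	orch,phsu
probenecid	C0033152	Probenecid	orch,phsu
sumatriptan	C0075632	Sumatriptan	orch,phsu
heparin	C0019134	Heparin	orch,phsu
ondansetron	C0061851	Ondansetron	orch,phsu
phenobarbital	C0031412	Phenobarbital	orch,phsu
carbamazepine	C0006949	Carbamazepine	orch,phsu
effect		Qualitative Concept	qlco
effects		Qualitative Concept	qlco
property		Qualitative Concept	qlco
properties		Qualitative Concept	qlco
activity		Qualitative Concept	qlco
activities		Qualitative Concept	qlco
action		Qualitative Concept	qlco
actions		Qualitative Concept	qlco
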