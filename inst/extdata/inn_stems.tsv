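suffix	family
azolam	Benzodiazepine derivative
azepam	Benzodiazepine derivative
prazole	Proton pump inhibitor
azole	Azole antifungal
floxacin	Fluoroquinolone antibacterial
oxacin	Quinolone antibacterial
cillin	Penicillin antibiotic
mycin	Streptomyces-derived antibiotic
cycline	Tetracycline antibiotic
oxetine	Fluoxetine-type antidepressant
olol	Beta-adrenergic blocker
terol	Beta2-adrenergic agonist
pril	ACE inhibitor
sartan	Angiotensin II receptor antagonist
statin	HMG-CoA reductase inhibitor
dipine	Dihydropyridine calcium channel blocker
tidine	H2-receptor antagonist
thiazide	Thiazide diuretic
semide	Furosemide-type diuretic
formin	Biguanide antidiabetic
triptan	Serotonin 5-HT1 agonist
parin	Heparin derivative
coxib	COX-2 selective inhibitor
profen	Ibuprofen-type anti-inflammatory
caine	Local anaesthetic
setron	Serotonin 5-HT3 antagonist
zosin	Alpha-adrenergic antagonist
afil	PDE5 inhibitor
vir	Antiviral
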