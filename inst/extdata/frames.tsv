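kind	class	anaphor_head	antecedents	template
anaphor	pronominal_personal	they	D1,D2,D3	{D1}, {D2} and {D3} should be coadministered with care{X}. They might increase the plasma concentration of {D4}.
anaphor	pronominal_personal	it	D1	{D1} strongly inhibits hepatic metabolism{X}. It may reduce the clearance of {D2}.
anaphor	pronominal_reflexive	itself	D1	{D1} itself does not inhibit the metabolism of {D2}.
anaphor	pronominal_relative	which	D1	Caution is advised with {D1}{X}, which may potentiate the effect of {D2}.
anaphor	pronominal_relative	that	D1	Patients receiving {D1}{X} that inhibits CYP2D6 should be monitored closely.
anaphor	pronominal_distributive	both	D1,D2	{D1} and {D2} prolong the QT interval{X}; both should be avoided.
anaphor	pronominal_distributive	each	D1,D2	{D1} and {D2} may interact{X}; each can elevate serum concentrations.
anaphor	pronominal_demonstrative	these	D1,D2	{D1} and {D2} are potent enzyme inducers{X}. These are known to reduce the efficacy of {D3}.
anaphor	pronominal_indefinite	all	D1,D2,D3	{D1}, {D2} and {D3} undergo extensive hepatic metabolism{X}. All require careful dosage adjustment.
anaphor	pronominal_indefinite	some	D1,D2	{D1} and {D2} may produce additive sedation{X}. Some are associated with respiratory depression.
anaphor	nominal_definite	{G}	D1	{D1} may interact with oral contraceptives{X}. The {G} should be discontinued before surgery.
anaphor	nominal_possessive	effects	D1	{D1} should be monitored closely{X} because of its sedative effects.
anaphor	nominal_possessive	effects	D1,D2	{D1} and {D2} should not be combined{X} because of their additive effects.
anaphor	nominal_distributive	{Gs}	D1,D2	{D1} and {D2} depress cardiac conduction{X}. Both {Gs} should be used cautiously.
anaphor	nominal_distributive	{G}	D1,D2	{D1} and {D2} may lower blood pressure{X}. Each {G} should be titrated slowly.
anaphor	nominal_demonstrative	{Gs}	D1,D2	{D1} and {D2} inhibit platelet aggregation{X}. These {Gs} may potentiate bleeding.
anaphor	nominal_demonstrative	{G}	D1	{D1} is a potent inhibitor of CYP3A4{X}. This {G} markedly increases exposure to {D2}.
anaphor	nominal_indefinite	{Gs}	D1,D2	{D1} and {D2} may cause marked hypotension{X}. All such {Gs} share this risk.
anaphor	nominal_indefinite	{G}	D1	{D1} can cause severe hypotension{X}. Another {G} of this class may be safer.
pleonastic		it		It is not known whether {D1} interacts with {D2}.
pleonastic		it		If it is not possible to discontinue {D1}, the dosage of {D2} should be reduced.
pleonastic		it		It does not appear that {D1} reduces the effectiveness of {D2}.
correlative			D1,D2	Coadministration of both {D1} and {D2} should be avoided.
correlative			D1,D2	Either {D1} or {D2} may be used as monotherapy.
correlative			D1,D2	Neither {D1} nor {D2} altered the pharmacokinetics of {D3}.
filler				Close observation is recommended during combination treatment.
filler				Patients should be observed for signs of toxicity.
filler				Careful dosage selection is warranted in this setting.
filler				No dosage adjustment is usually necessary.
filler				Prescribers should consider the expected benefit of treatment.
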