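# Synthetic reconstruction of a Synechocystis central-carbon-metabolism
# kinetic network: Calvin cycle with photorespiratory, glycogen, lower-
# glycolysis and biosynthetic drains, plus light-driven ATP/NADPH supply
# and mass-action phosphate supply. Concentration ranges are NET-style
# bounds around a reference state; all values are synthetic stand-ins.
[metabolites]
id	name	role	lower_mM	upper_mM
RUBP	ribulose-1,5-bisphosphate	internal	0.06	1.5
PGA	3-phosphoglycerate	internal	0.4	10
BPG	1,3-bisphosphoglycerate	internal	0.01	0.25
GAP	glyceraldehyde-3-phosphate	internal	0.01	0.25
DHAP	dihydroxyacetone phosphate	internal	0.1	2.5
FBP	fructose-1,6-bisphosphate	internal	0.04	1
F6P	fructose-6-phosphate	internal	0.1	2.5
G6P	glucose-6-phosphate	internal	0.2	5
E4P	erythrose-4-phosphate	internal	0.01	0.25
X5P	xylulose-5-phosphate	internal	0.02	0.5
S7P	sedoheptulose-7-phosphate	internal	0.04	1
SBP	sedoheptulose-1,7-bisphosphate	internal	0.02	0.5
R5P	ribose-5-phosphate	internal	0.02	0.5
RU5P	ribulose-5-phosphate	internal	0.01	0.25
PEP	phosphoenolpyruvate	internal	0.06	1.5
PYR	pyruvate	internal	0.1	2.5
PGLYC	2-phosphoglycolate	internal	0.01	0.25
ATP	ATP	internal	0.6	15
ADP	ADP	internal	0.1	2.5
NADPH	NADPH	internal	0.1	2.5
NADP	NADP+	internal	0.01	0.25
PI	orthophosphate	internal	2	50
CO2	carbon dioxide	external	0.125	0.5
O2	oxygen	external	0.125	0.5
H2O	water	external	0.5	2
H	proton	external	0.5	2
NH4	ammonium	external	0.5	2
PI_EXT	external phosphate	external	5	20
PPI	pyrophosphate	external	0.5	2
GLYCOLATE	glycolate	external	0.5	2
ACCOA	acetyl-CoA	external	0.25	1
GLYCOGEN	glycogen	external	0.5	2
NUCL	nucleotide pool	external	0.5	2
AROM	aromatic precursor pool	external	0.5	2
LIPID	lipid precursor pool	external	0.5	2
OAA	oxaloacetate	external	0.5	2

[reactions]
id	rate_law	dg0_kJ_mol	hill_substrate	equation
RBC_C	irreversible_mm	-25.022	NA	RUBP + CO2 + H2O -> 2 PGA
RBC_O	irreversible_mm	-15.725	NA	RUBP + O2 -> PGA + PGLYC
PGK	reversible_mm	8.813	NA	PGA + ATP <-> BPG + ADP
GAPDH	reversible_mm	-5	NA	BPG + NADPH <-> GAP + NADP + PI
TPI	reversible_mm	-10.803	NA	GAP <-> DHAP
FBA	reversible_mm	-10.241	NA	GAP + DHAP <-> FBP
FBPASE	irreversible_mm	-23.113	FBP	FBP + H2O -> F6P + PI
TKT1	reversible_mm	-0.944	NA	F6P + GAP <-> X5P + E4P
SBA	reversible_mm	-8.494	NA	DHAP + E4P <-> SBP
SBPASE	irreversible_mm	-22.55	SBP	SBP + H2O -> S7P + PI
TKT2	reversible_mm	-5	NA	S7P + GAP <-> X5P + R5P
RPI	reversible_mm	-3.253	NA	R5P <-> RU5P
RPE	reversible_mm	-3.253	NA	X5P <-> RU5P
PRK	irreversible_mm	-15	NA	RU5P + ATP -> RUBP + ADP
PGI	reversible_mm	-6.747	NA	F6P <-> G6P
PGP	irreversible_mm	-28.354	NA	PGLYC + H2O -> GLYCOLATE + PI
ENO	reversible_mm	0.781	NA	PGA <-> PEP
PYK	irreversible_mm	-25.803	NA	PEP + ADP -> PYR + ATP
PDH	irreversible_mm	-27.309	NA	PYR + NADP -> ACCOA + CO2 + NADPH
GLGSYN	irreversible_mm	-10.484	NA	G6P + ATP -> GLYCOGEN + ADP + PPI
R5PSINK	irreversible_mm	-16.287	NA	R5P + ATP + NH4 -> NUCL + ADP
E4PSINK	irreversible_mm	-22.55	NA	E4P -> AROM
GAPSINK	irreversible_mm	-22.55	NA	GAP -> LIPID
PEPC	irreversible_mm	-37.332	NA	PEP + CO2 -> OAA + PI
ATPSYN	irreversible_mm	NA	NA	ADP + PI + H -> ATP + H2O
NADPHSYN	irreversible_mm	NA	NA	NADP -> NADPH
PISUPPLY	mass_action	NA	NA	PI_EXT -> PI
ATPMAINT	irreversible_mm	NA	NA	ATP + H2O -> ADP + PI
NADPHMAINT	irreversible_mm	NA	NA	NADPH -> NADP

[regulations]
reaction	kind	effector	constant_mM	max_km_reduction	variant
FBPASE	km_activation	GAP	0.5	0.75	fsbpase
FBPASE	noncompetitive_inhibition	NADPH	3	NA	fsbpase
SBPASE	km_activation	GAP	0.5	0.75	fsbpase
SBPASE	noncompetitive_inhibition	NADPH	3	NA	fsbpase
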