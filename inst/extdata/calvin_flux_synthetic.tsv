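reaction	v_mM_min
RBC_C	18.5
RBC_O	1
PGK	36.5
GAPDH	36.5
TPI	14.5
FBA	8
FBPASE	8
TKT1	7
SBA	6.5
SBPASE	6.5
TKT2	6.5
RPI	6
RPE	13.5
PRK	19.5
PGI	1
PGP	1
ENO	1.5
PYK	1
PDH	1
GLGSYN	1
R5PSINK	0.5
E4PSINK	0.5
GAPSINK	0.5
PEPC	0.5
ATPSYN	58.5
NADPHSYN	36.5
PISUPPLY	4
ATPMAINT	2
NADPHMAINT	1
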