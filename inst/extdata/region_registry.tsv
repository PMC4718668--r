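region_id	full_name	area_group	x	y
Cg1	cingulate cortex, area 1	prefrontal cortex	1.0	10.0
PrL	prelimbic cortex	prefrontal cortex	2.0	10.0
IL	infralimbic cortex	prefrontal cortex	3.0	10.0
VLO	ventrolateral/orbital cortex	prefrontal cortex	4.0	10.0
M1	primary motor cortex	sensorimotor cortex	5.5	10.0
M2	secondary motor cortex	sensorimotor cortex	6.5	10.0
S1	primary sensory cortex	sensorimotor cortex	7.5	10.0
cM1	caudal primary motor cortex	sensorimotor cortex	8.5	10.0
AI	agranular insular cortex	sensorimotor cortex	9.5	10.0
cAI	caudal agranular insular cortex	sensorimotor cortex	10.5	10.0
dmCPu	dorsomedial caudate putamen	striatum	5.0	7.5
dlCPu	dorsolateral caudate putamen	striatum	7.0	7.5
vmCPu	ventromedial caudate putamen	striatum	5.0	6.0
vlCPu	ventrolateral caudate putamen	striatum	7.0	6.0
NAcC	nucleus accumbens core	striatum	5.5	4.5
NAcSh	nucleus accumbens shell	striatum	6.8	4.5
CA1	hippocampal field CA1	hippocampus/septum	1.0	7.5
CA2	hippocampal field CA2	hippocampus/septum	1.0	6.3
CA3	hippocampal field CA3	hippocampus/septum	1.0	5.1
DG	dentate gyrus	hippocampus/septum	1.0	3.9
MS	medial septum	hippocampus/septum	2.6	6.0
LS	lateral septum	hippocampus/septum	2.6	4.6
BNST	bed nucleus of the stria terminalis	amygdala/hypothalamus	4.0	1.5
PVN	paraventricular nucleus of the hypothalamus	amygdala/hypothalamus	5.6	1.5
BLA	basolateral amygdala	amygdala/hypothalamus	7.2	1.5
CeA	central nucleus of the amygdala	amygdala/hypothalamus	8.8	1.5
MeA	medial nucleus of the amygdala	amygdala/hypothalamus	10.4	1.5
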