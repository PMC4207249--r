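pattern_id	smarts	description
rhodanine	O=C1CSC(=S)N1	rhodanine (2-thioxothiazolidin-4-one) core
ene_rhodanine	O=C1C(=C)SC(=S)N1	exocyclic alkylidene rhodanine
quinone_para	O=C1C=CC(=O)C=C1	para-quinone
catechol	Oc1ccccc1O	catechol (1,2-dihydroxybenzene)
hydroxyphenyl_hydrazone	Oc1ccccc1C=NN	2-hydroxyphenyl hydrazone
azo_aromatic	cN=Nc	aromatic azo linkage
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=C	alkylidene barbiturate
ene_thiazolidinone	O=C1C(=C)SC(=N)N1	alkylidene 2-imino-thiazolidin-4-one
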