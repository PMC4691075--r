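pathway_id	S6_S0	R6_R0	R0_S0	R6_S6	reported_resistance_class	reported_susceptibility_class
Betanidin degradation		down		lower	I	none
Cytokinins degradation		down		lower	I	none
Glutamate degradation III		down		lower	I	none
IAA conjugate biosynthesis I		up		higher	I	none
IAA conjugate biosynthesis II		up		higher	I	none
Spermine biosynthesis		up		higher	I	none
Very long chain fatty acid biosynthesis		up		higher	I	none
Momilactone biosynthesis		up		higher	I	none
Flavonoid biosynthesis		down	higher	higher	II	none
Mixed acid fermentation		down	higher	higher	II	none
Pinobanksin biosynthesis		down	higher	higher	II	none
Aminopropanol biosynthesis		down	lower	lower	II	none
Salicylate biosynthesis		down	lower	lower	II	none
Serine biosynthesis		down	lower	lower	II	none
Threonine degradation II		down	lower	lower	II	none
Threonine degradation III (to methylglyoxal)		down	lower	lower	II	none
Reductive TCA cycle I		up	higher	higher	II	none
13-LOX and 13-HPL pathway		up	lower	lower	II	none
Divinyl ether biosynthesis II (13-LOX)		up	lower	lower	II	none
Ureide biosynthesis	up	down	lower	lower	III	III
phenylalanine degradation III	up	down		lower	III	III
methylerythritol phosphate pathway	down		lower	lower	none	II
thiamine biosynthesis	down		lower	lower	none	II
lysine degradation I	up		higher	higher	none	II
phospholipid biosynthesis II	up		lower	lower	none	II
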