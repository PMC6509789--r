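reaction_id	equation	lower	upper	gpr
LHC	photon -> 2 atp	0	1e+06	gLHC
ACT	ac -> c + red	0	1e+06	(gACT1 or gACT2)
OX	c -> co2 + red	0	1e+06	gOX
FIX_A	3 atp + co2 + red -> c	0	1e+06	(gFA1 and gFA2)
FIX_B	2 atp + co2 + red -> c	0	1e+06	gFB
BIOSYN	15 atp + 10 c + red -> biomass	0	1e+06	gBIO
NIT	2 atp + red -> h2	0	1e+06	(gNIT1 and gNIT2)
BYP	c + red -> byp	0	1e+06	gBYP
EX_photon	photon <->	-50	0	
EX_ac	ac <->	-10	0	
EX_co2	co2 ->	0	1e+06	
EX_h2	h2 ->	0	1e+06	
EX_byp	byp ->	0	1e+06	
EX_biomass	biomass ->	0	1e+06	
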