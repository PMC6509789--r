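id	name	compartment	formula	charge	is_external	electrons
photon	photon	c			FALSE	0
atp	ATP (energy token)	c			FALSE	0
ac	acetate unit (per C)	c	CH4O2	0	FALSE	
c	fixed carbon unit	c	CH2O2	0	FALSE	
red	2-electron reduction carrier	c	H2	0	FALSE	
co2	CO2	c	CO2	0	FALSE	
h2	hydrogen gas	c	H2	0	FALSE	
byp	reduced byproduct unit	c	CH4O2	0	FALSE	
biomass	biomass unit	c	C10H22O20	0	FALSE	
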