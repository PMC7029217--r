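component_id	coefficient_mmol_per_g	formula	charge
phb_c	6.62688474124445	C4H6O2	0
glycogen_c	1.65672118531111	C6H10O5	0
glu__L_c	0.883584632165927	C5H8NO4	-1
nh4_c	1.10448079020741	H4N	1
pi_c	0.110448079020741	HO4P	-2
fe2_c	0.0220896158041482	Fe	2
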