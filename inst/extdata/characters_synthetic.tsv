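species	Hairless	SuH_CtBP	SuH_Gro	MTA_linked
Oligostraca	1	1	1	1
Branchiopoda	1	1	1	1
Copepoda	1	1	1	0
Malacostraca	1	1	1	1
Collembola	1	1	1	1
Diplura	1	1	1	1
Archaeognatha	1	1	1	1
Zygentoma	1	1	1	1
Ephemeroptera	1	1	1	1
Odonata	1	1	1	1
Neoptera	1	0	0	1
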