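# promoterlogic parameter file (class: plf_params)
basal_fraction	0.0080000000000000002
ahl_luxr_halfsat	1
luxr_dna_halfsat	300
hill_m	2
hill_n	1.45
ahl_density_const	0.040000000000000001
density	0.10000000000000001
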