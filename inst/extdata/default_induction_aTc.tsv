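# promoterlogic parameter file (class: hill_params)
basal	8
span	800
halfsat	10
hill	2
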