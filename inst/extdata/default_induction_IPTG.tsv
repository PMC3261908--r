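# promoterlogic parameter file (class: hill_params)
basal	12
span	1800
halfsat	80
hill	1.6000000000000001
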