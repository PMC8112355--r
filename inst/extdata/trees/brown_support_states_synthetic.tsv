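# SYNTHETIC support states of the brown panel, derived from the
# packaged detection table via the strong/weak/none rule.
tip	state
Ectocarpus-siliculosus	strong
Ectocarpus-subulatus	strong
Ectocarpus-fasciculatus	none
Ectocarpus-crouaniorum	none
Pylaiella-littoralis	weak
Saccharina-latissima	strong
Laminaria-digitata	weak
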