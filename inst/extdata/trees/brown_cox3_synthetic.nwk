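((((Ectocarpus-siliculosus:0.05,Ectocarpus-crouaniorum:0.05):0.03,(Ectocarpus-subulatus:0.04,Ectocarpus-fasciculatus:0.04):0.04):0.08,Pylaiella-littoralis:0.16):0.09,(Saccharina-latissima:0.12,Laminaria-digitata:0.12):0.13);
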