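name	removed	added	context	relaxation
sterone-d1-2-desaturation	bond(c1,c2,single)	bond(c1,c2,double)	atom(c1,carbon) atom(c2,carbon) bond(c1,c10,single) bond(c2,c3,single)	strict
sterone-23-hydroxylation		atom(o2,oxygen) bond(c23,o2,double)	atom(c23,carbon) bond(c22,c23,single) bond(c23,c24,single)	strict
sterone-3-reduction	bond(c3,o1,double)	bond(c3,o1,single)	atom(c3,carbon) atom(o1,oxygen)	strict
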