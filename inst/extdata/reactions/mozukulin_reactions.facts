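# Boundary into the mozukulin branch: cholesterol-oxidase-type
# 3-dehydrogenation with Delta5->Delta4 isomerization on desmosterol.
reaction(sterol-3-dehydrogenation-d4-isomerization, desmosterol, cholesta-4-24-dien-3-one).
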