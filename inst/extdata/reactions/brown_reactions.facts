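# Known reactions of the brown algal sterol model: one exemplar
# substrate/product pair per molecular transformation. The reaction name
# is the transformation name; the same transformation may recur on other
# substrates by deduction.
reaction(squalene-cyclization, squalene, cycloartenol).
reaction(sterol-4-demethylation-i, cycloartenol, 31-norcycloartenol).
reaction(cyclopropane-ring-opening, 31-norcycloartenol, 31-norlanosterol).
reaction(sterol-14-demethylation, 31-norlanosterol, 4a-methylzymosterol).
reaction(sterol-4-demethylation-ii, 4a-methylzymosterol, zymosterol).
reaction(sterol-d8-d7-isomerization, zymosterol, cholesta-7-24-dienol).
reaction(sterol-5-desaturation, lathosterol, 7-dehydrocholesterol).
reaction(sterol-d7-reduction, 7-dehydrocholesterol, cholesterol).
reaction(sterol-d24-reduction, desmosterol, cholesterol).
reaction(sterol-24-methylation, desmosterol, 24-methylenecholesterol).
reaction(sterol-28-methylation, 24-methylenecholesterol, fucosterol).
reaction(sterol-d24-28-reduction, 24-methylenecholesterol, 24-methylcholesterol).
reaction(sterol-22-desaturation, 24-methylcholesterol, 24-methylcholest-22-enol).
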