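# Presence/absence of panel compounds per species. Statements not
# fixed by the published profiling text (per-species cholesterol /
# desmosterol / 22-enol splits) are SYNTHETIC plausible assignments.
species	molecule	status
Ectocarpus-siliculosus	squalene	detected
Ectocarpus-subulatus	squalene	detected
Ectocarpus-fasciculatus	squalene	detected
Ectocarpus-crouaniorum	squalene	detected
Pylaiella-littoralis	squalene	detected
Saccharina-latissima	squalene	detected
Laminaria-digitata	squalene	detected
Chondrus-crispus	squalene	detected
Mastocarpus-stellatus	squalene	detected
Palmaria-palmata	squalene	detected
Ulva-sp	squalene	detected
Ectocarpus-siliculosus	cycloartenol	detected
Ectocarpus-subulatus	cycloartenol	detected
Ectocarpus-fasciculatus	cycloartenol	detected
Ectocarpus-crouaniorum	cycloartenol	detected
Pylaiella-littoralis	cycloartenol	detected
Saccharina-latissima	cycloartenol	detected
Mastocarpus-stellatus	cycloartenol	detected
Palmaria-palmata	cycloartenol	detected
Ulva-sp	cycloartenol	detected
Laminaria-digitata	cycloartenol	not_detected
Chondrus-crispus	cycloartenol	not_detected
Palmaria-palmata	zymosterol	detected
Ectocarpus-subulatus	zymosterol	detected
Ectocarpus-siliculosus	zymosterol	not_detected
Ectocarpus-fasciculatus	zymosterol	not_detected
Ectocarpus-crouaniorum	zymosterol	not_detected
Pylaiella-littoralis	zymosterol	not_detected
Saccharina-latissima	zymosterol	not_detected
Laminaria-digitata	zymosterol	not_detected
Chondrus-crispus	zymosterol	not_detected
Mastocarpus-stellatus	zymosterol	not_detected
Ulva-sp	zymosterol	not_detected
Ectocarpus-siliculosus	lanosterol	not_detected
Ectocarpus-subulatus	lanosterol	not_detected
Ectocarpus-fasciculatus	lanosterol	not_detected
Ectocarpus-crouaniorum	lanosterol	not_detected
Pylaiella-littoralis	lanosterol	not_detected
Saccharina-latissima	lanosterol	not_detected
Laminaria-digitata	lanosterol	not_detected
Chondrus-crispus	lanosterol	not_detected
Mastocarpus-stellatus	lanosterol	not_detected
Palmaria-palmata	lanosterol	not_detected
Ulva-sp	lanosterol	not_detected
Chondrus-crispus	lathosterol	detected
Mastocarpus-stellatus	lathosterol	detected
Palmaria-palmata	lathosterol	detected
Ectocarpus-siliculosus	lathosterol	not_detected
Ectocarpus-subulatus	lathosterol	not_detected
Ectocarpus-fasciculatus	lathosterol	not_detected
Ectocarpus-crouaniorum	lathosterol	not_detected
Pylaiella-littoralis	lathosterol	not_detected
Saccharina-latissima	lathosterol	not_detected
Laminaria-digitata	lathosterol	not_detected
Ulva-sp	lathosterol	not_detected
Chondrus-crispus	24-ethylcholesterol	detected
Mastocarpus-stellatus	24-ethylcholesterol	detected
Palmaria-palmata	24-ethylcholesterol	detected
Ectocarpus-siliculosus	24-ethylcholesterol	not_detected
Ectocarpus-subulatus	24-ethylcholesterol	not_detected
Ectocarpus-fasciculatus	24-ethylcholesterol	not_detected
Ectocarpus-crouaniorum	24-ethylcholesterol	not_detected
Pylaiella-littoralis	24-ethylcholesterol	not_detected
Saccharina-latissima	24-ethylcholesterol	not_detected
Laminaria-digitata	24-ethylcholesterol	not_detected
Ulva-sp	24-ethylcholesterol	not_detected
Ectocarpus-siliculosus	fucosterol	detected
Ectocarpus-subulatus	fucosterol	detected
Ectocarpus-fasciculatus	fucosterol	detected
Ectocarpus-crouaniorum	fucosterol	detected
Pylaiella-littoralis	fucosterol	detected
Saccharina-latissima	fucosterol	detected
Laminaria-digitata	fucosterol	detected
Ulva-sp	fucosterol	detected
Chondrus-crispus	fucosterol	not_detected
Mastocarpus-stellatus	fucosterol	not_detected
Palmaria-palmata	fucosterol	not_detected
Ectocarpus-siliculosus	24-methylcholesterol	detected
Ectocarpus-subulatus	24-methylcholesterol	detected
Ectocarpus-fasciculatus	24-methylcholesterol	detected
Ectocarpus-crouaniorum	24-methylcholesterol	detected
Pylaiella-littoralis	24-methylcholesterol	detected
Saccharina-latissima	24-methylcholesterol	detected
Laminaria-digitata	24-methylcholesterol	detected
Chondrus-crispus	24-methylcholesterol	not_detected
Mastocarpus-stellatus	24-methylcholesterol	not_detected
Palmaria-palmata	24-methylcholesterol	not_detected
Ulva-sp	24-methylcholesterol	unknown
Ectocarpus-siliculosus	cholesterol	detected
Ectocarpus-subulatus	cholesterol	detected
Saccharina-latissima	cholesterol	detected
Laminaria-digitata	cholesterol	detected
Pylaiella-littoralis	cholesterol	detected
Chondrus-crispus	cholesterol	detected
Mastocarpus-stellatus	cholesterol	detected
Palmaria-palmata	cholesterol	detected
Ectocarpus-fasciculatus	cholesterol	not_detected
Ectocarpus-crouaniorum	cholesterol	not_detected
Ulva-sp	cholesterol	not_detected
Ectocarpus-siliculosus	desmosterol	detected
Ectocarpus-subulatus	desmosterol	detected
Saccharina-latissima	desmosterol	detected
Palmaria-palmata	desmosterol	detected
Ectocarpus-fasciculatus	desmosterol	not_detected
Ectocarpus-crouaniorum	desmosterol	not_detected
Pylaiella-littoralis	desmosterol	not_detected
Laminaria-digitata	desmosterol	not_detected
Chondrus-crispus	desmosterol	not_detected
Mastocarpus-stellatus	desmosterol	not_detected
Ulva-sp	desmosterol	not_detected
Ectocarpus-siliculosus	24-methylcholest-22-enol	detected
Ectocarpus-subulatus	24-methylcholest-22-enol	detected
Saccharina-latissima	24-methylcholest-22-enol	detected
Pylaiella-littoralis	24-methylcholest-22-enol	detected
Ectocarpus-fasciculatus	24-methylcholest-22-enol	not_detected
Ectocarpus-crouaniorum	24-methylcholest-22-enol	not_detected
Laminaria-digitata	24-methylcholest-22-enol	not_detected
Chondrus-crispus	24-methylcholest-22-enol	not_detected
Mastocarpus-stellatus	24-methylcholest-22-enol	not_detected
Palmaria-palmata	24-methylcholest-22-enol	not_detected
Ulva-sp	24-methylcholest-22-enol	not_detected
Ectocarpus-siliculosus	24-ethylcholest-22-enol	detected
Ectocarpus-subulatus	24-ethylcholest-22-enol	detected
Saccharina-latissima	24-ethylcholest-22-enol	detected
Laminaria-digitata	24-ethylcholest-22-enol	detected
Pylaiella-littoralis	24-ethylcholest-22-enol	detected
Ectocarpus-fasciculatus	24-ethylcholest-22-enol	not_detected
Ectocarpus-crouaniorum	24-ethylcholest-22-enol	not_detected
Chondrus-crispus	24-ethylcholest-22-enol	not_detected
Mastocarpus-stellatus	24-ethylcholest-22-enol	not_detected
Palmaria-palmata	24-ethylcholest-22-enol	not_detected
Ulva-sp	24-ethylcholest-22-enol	not_detected
Ectocarpus-siliculosus	7-dehydrocholesterol	not_detected
Ectocarpus-subulatus	7-dehydrocholesterol	not_detected
Ectocarpus-fasciculatus	7-dehydrocholesterol	not_detected
Ectocarpus-crouaniorum	7-dehydrocholesterol	not_detected
Pylaiella-littoralis	7-dehydrocholesterol	not_detected
Saccharina-latissima	7-dehydrocholesterol	not_detected
Laminaria-digitata	7-dehydrocholesterol	not_detected
Chondrus-crispus	7-dehydrocholesterol	not_detected
Mastocarpus-stellatus	7-dehydrocholesterol	not_detected
Palmaria-palmata	7-dehydrocholesterol	not_detected
Ulva-sp	7-dehydrocholesterol	not_detected
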