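transformation	substrate	product	optional
sterol-4-demethylation-i	cycloartenol	31-norcycloartenol	FALSE
cyclopropane-ring-opening	31-norcycloartenol	31-norlanosterol	FALSE
sterol-14-demethylation	31-norlanosterol	4a-methylzymosterol	FALSE
sterol-4-demethylation-ii	4a-methylzymosterol	zymosterol	FALSE
sterol-d8-d7-isomerization	zymosterol	cholesta-7-24-dienol	FALSE
sterol-5-desaturation	cholesta-7-24-dienol	7-dehydrodesmosterol	FALSE
sterol-d7-reduction	7-dehydrodesmosterol	desmosterol	FALSE
sterol-d24-reduction	desmosterol	cholesterol	FALSE
sterol-24-methylation	desmosterol	24-methylenecholesterol	FALSE
sterol-28-methylation	24-methylenecholesterol	fucosterol	FALSE
sterol-d24-28-reduction	24-methylenecholesterol	24-methylcholesterol	FALSE
sterol-22-desaturation	24-methylcholesterol	24-methylcholest-22-enol	FALSE
sterol-d24-28-reduction	fucosterol	24-ethylcholesterol	FALSE
sterol-22-desaturation	24-ethylcholesterol	24-ethylcholest-22-enol	FALSE
squalene-cyclization	squalene	cycloartenol	TRUE
sterol-d8-d7-isomerization	4a-methylzymosterol	4a-methylcholesta-7-24-dienol	TRUE
sterol-4-demethylation-ii	4a-methylcholesta-7-24-dienol	cholesta-7-24-dienol	TRUE
sterol-d24-reduction	cholesta-7-24-dienol	lathosterol	TRUE
sterol-5-desaturation	lathosterol	7-dehydrocholesterol	TRUE
sterol-d7-reduction	7-dehydrocholesterol	cholesterol	TRUE
sterol-d24-reduction	7-dehydrodesmosterol	7-dehydrocholesterol	TRUE
sterol-d24-reduction	cycloartenol	cycloartanol	TRUE
cyclopropane-ring-opening	cycloartenol	lanosterol	TRUE
sterol-4-demethylation-i	lanosterol	31-norlanosterol	TRUE
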