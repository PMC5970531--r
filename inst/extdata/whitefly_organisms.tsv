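organism_id	genus	label
Portiera	Portiera	Portiera (obligate)
Hamiltonella_MEDQ1	Hamiltonella	Hamiltonella MED-Q1
Hamiltonella_MEAM1	Hamiltonella	Hamiltonella MEAM1
Rickettsia_MEAM1USA	Rickettsia	Rickettsia MEAM1-USA
Rickettsia_MEAM1CN	Rickettsia	Rickettsia MEAM1-China
Cardinium_MEDQ1	Cardinium	Cardinium MED-Q1
Wolbachia_MEDQ2	Wolbachia	Wolbachia MED-Q2
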