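a	b	occurring
Hamiltonella_MEDQ1	Cardinium_MEDQ1	TRUE
Hamiltonella_MEDQ1	Wolbachia_MEDQ2	TRUE
Hamiltonella_MEDQ1	Portiera	TRUE
Hamiltonella_MEAM1	Rickettsia_MEAM1USA	TRUE
Hamiltonella_MEAM1	Rickettsia_MEAM1CN	TRUE
Hamiltonella_MEAM1	Portiera	TRUE
Rickettsia_MEAM1USA	Wolbachia_MEDQ2	TRUE
Rickettsia_MEAM1USA	Portiera	TRUE
Rickettsia_MEAM1CN	Wolbachia_MEDQ2	TRUE
Rickettsia_MEAM1CN	Portiera	TRUE
Cardinium_MEDQ1	Portiera	TRUE
Wolbachia_MEDQ2	Portiera	TRUE
Hamiltonella_MEDQ1	Rickettsia_MEAM1USA	FALSE
Hamiltonella_MEDQ1	Rickettsia_MEAM1CN	FALSE
Hamiltonella_MEAM1	Cardinium_MEDQ1	FALSE
Hamiltonella_MEAM1	Wolbachia_MEDQ2	FALSE
Rickettsia_MEAM1USA	Cardinium_MEDQ1	FALSE
Rickettsia_MEAM1CN	Cardinium_MEDQ1	FALSE
Cardinium_MEDQ1	Wolbachia_MEDQ2	FALSE
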