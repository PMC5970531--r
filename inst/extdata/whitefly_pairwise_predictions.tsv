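row_id	col_id	comp_host	comp_hp	score
Hamiltonella_MEDQ1	Hamiltonella_MEAM1	0	0	0.32
Hamiltonella_MEDQ1	Rickettsia_MEAM1USA	22	17	0.19
Hamiltonella_MEDQ1	Rickettsia_MEAM1CN	21	20	0.2
Hamiltonella_MEDQ1	Cardinium_MEDQ1	0	0	0.08
Hamiltonella_MEDQ1	Wolbachia_MEDQ2	11	14	0.22
Hamiltonella_MEDQ1	Portiera	13	NA	0.06
Hamiltonella_MEAM1	Hamiltonella_MEDQ1	0	0	0.97
Hamiltonella_MEAM1	Rickettsia_MEAM1USA	19	20	0.17
Hamiltonella_MEAM1	Rickettsia_MEAM1CN	20	21	0.19
Hamiltonella_MEAM1	Cardinium_MEDQ1	0	0	0.05
Hamiltonella_MEAM1	Wolbachia_MEDQ2	18	7	0.19
Hamiltonella_MEAM1	Portiera	14	NA	0.05
Rickettsia_MEAM1USA	Hamiltonella_MEDQ1	22	17	0.2
Rickettsia_MEAM1USA	Hamiltonella_MEAM1	19	20	0.2
Rickettsia_MEAM1USA	Rickettsia_MEAM1CN	0	0	0.95
Rickettsia_MEAM1USA	Cardinium_MEDQ1	9	9	0.09
Rickettsia_MEAM1USA	Wolbachia_MEDQ2	6	4	0.11
Rickettsia_MEAM1USA	Portiera	14	NA	0.07
Rickettsia_MEAM1CN	Hamiltonella_MEDQ1	21	20	0.21
Rickettsia_MEAM1CN	Hamiltonella_MEAM1	20	21	0.21
Rickettsia_MEAM1CN	Rickettsia_MEAM1USA	0	0	1
Rickettsia_MEAM1CN	Cardinium_MEDQ1	10	11	0.12
Rickettsia_MEAM1CN	Wolbachia_MEDQ2	8	7	0.14
Rickettsia_MEAM1CN	Portiera	13	NA	0.07
Cardinium_MEDQ1	Hamiltonella_MEDQ1	0	0	0.17
Cardinium_MEDQ1	Hamiltonella_MEAM1	0	0	0.15
Cardinium_MEDQ1	Rickettsia_MEAM1USA	9	9	0.1
Cardinium_MEDQ1	Rickettsia_MEAM1CN	10	11	0.12
Cardinium_MEDQ1	Wolbachia_MEDQ2	9	9	0.12
Cardinium_MEDQ1	Portiera	13	NA	0.15
Wolbachia_MEDQ2	Hamiltonella_MEDQ1	11	14	0.38
Wolbachia_MEDQ2	Hamiltonella_MEAM1	18	7	0.36
Wolbachia_MEDQ2	Rickettsia_MEAM1USA	6	4	0.3
Wolbachia_MEDQ2	Rickettsia_MEAM1CN	8	7	0.34
Wolbachia_MEDQ2	Cardinium_MEDQ1	9	9	0.14
Wolbachia_MEDQ2	Portiera	8	NA	0.12
Portiera	Hamiltonella_MEDQ1	13	NA	0.25
Portiera	Hamiltonella_MEAM1	14	NA	0.25
Portiera	Rickettsia_MEAM1USA	14	NA	0.25
Portiera	Rickettsia_MEAM1CN	13	NA	0.25
Portiera	Cardinium_MEDQ1	13	NA	0.25
Portiera	Wolbachia_MEDQ2	8	NA	0.25
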