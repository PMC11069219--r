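code_low	code_high	iarc8_group	who5_group	wildcard
8000	8005	unspecified	O&U	TRUE
8010	8011	unspecified	O&U	TRUE
8012	8014	large_cell	LCC	FALSE
8015	8015	unspecified	O&U	TRUE
8020	8022	unspecified	O&U	TRUE
8030	8040	other_carcinoma	O&U	FALSE
8041	8045	small_cell	SCLC	FALSE
8046	8046	other_carcinoma	O&U	FALSE
8050	8050	unspecified	O&U	TRUE
8051	8084	squamous	SCC	FALSE
8090	8110	other_carcinoma	O&U	FALSE
8120	8131	squamous	SCC	FALSE
8140	8149	adenocarcinoma	AC	FALSE
8150	8157	other_carcinoma	O&U	FALSE
8160	8162	adenocarcinoma	AC	FALSE
8170	8180	other_carcinoma	O&U	FALSE
8190	8221	adenocarcinoma	AC	FALSE
8230	8249	other_carcinoma	O&U	FALSE
8250	8337	adenocarcinoma	AC	FALSE
8340	8347	other_carcinoma	O&U	FALSE
8350	8551	adenocarcinoma	AC	FALSE
8560	8562	other_carcinoma	O&U	FALSE
8570	8576	adenocarcinoma	AC	FALSE
8580	8671	other_carcinoma	O&U	FALSE
8680	8713	sarcoma	O&U	FALSE
8720	8790	other_specified	O&U	FALSE
8800	8921	sarcoma	O&U	FALSE
8930	8936	other_specified	O&U	FALSE
8940	8941	adenocarcinoma	AC	FALSE
8950	8983	other_specified	O&U	FALSE
8990	8991	sarcoma	O&U	FALSE
9000	9030	other_specified	O&U	FALSE
9040	9044	sarcoma	O&U	FALSE
9050	9055	sarcoma	O&U	FALSE
9060	9110	other_specified	O&U	FALSE
9120	9252	sarcoma	O&U	FALSE
9260	9365	other_specified	O&U	FALSE
9370	9373	sarcoma	O&U	FALSE
9380	9539	other_specified	O&U	FALSE
9540	9582	sarcoma	O&U	FALSE
9590	9993	other_specified	O&U	FALSE
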