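# Worked-example pedigree of the released soybean cultivar Nannong 32.
# Only the immediate parents (Nannong 87-23, Chuxiu), the seven terminal
# ancestors with their nuclear contributions, and the cytoplasmic line are
# published; the SYN-CROSS-* intermediate lines are synthetic placeholders
# reconstructing a topology consistent with those values.
id	name	method	female_or_source	male	ecoregion	period
Nannong 32	Nannong 32	cross	Nannong 87-23	Chuxiu	SC	P2006_2015
Nannong 87-23	Nannong 87-23	cross	SYN-CROSS-A	73-01-1	SC	UNKNOWN
SYN-CROSS-A	SYN-CROSS-A	cross	Fengxiansuidaohuang	51-83	SC	UNKNOWN
Chuxiu	Chuxiu	cross	Huaiyindasili	SYN-CROSS-B	SC	UNKNOWN
SYN-CROSS-B	SYN-CROSS-B	cross	Dangshanwandousha	SYN-CROSS-C	SC	UNKNOWN
SYN-CROSS-C	SYN-CROSS-C	cross	Tongshantianedan	Mamotan	HHH	UNKNOWN
73-01-1	73-01-1	terminal	.	.	SC	UNKNOWN
Huaiyindasili	Huaiyindasili	terminal	.	.	SC	UNKNOWN
Fengxiansuidaohuang	Fengxiansuidaohuang	terminal	.	.	SC	UNKNOWN
51-83	51-83	terminal	.	.	SC	UNKNOWN
Dangshanwandousha	Dangshanwandousha	terminal	.	.	HHH	UNKNOWN
Tongshantianedan	Tongshantianedan	terminal	.	.	HHH	UNKNOWN
Mamotan	Mamotan	terminal	.	.	FOREIGN	UNKNOWN
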