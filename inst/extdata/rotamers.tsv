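aa	name	chi1	chi2	freq
SER	p	62	NA	0.48
SER	t	-177	NA	0.22
SER	m	-65	NA	0.29
THR	p	62	NA	0.49
THR	t	-175	NA	0.07
THR	m	-65	NA	0.43
ASN	p-10	62	-10	0.07
ASN	p30	62	30	0.09
ASN	t-20	-174	-20	0.12
ASN	t30	-177	30	0.15
ASN	m-20	-65	-20	0.18
ASN	m-80	-65	-75	0.10
ASN	m120	-65	120	0.05
ASP	p-10	62	-10	0.10
ASP	p30	62	30	0.09
ASP	t0	-177	0	0.21
ASP	m-20	-70	-15	0.51
PHE	p90	62	90	0.13
PHE	t80	-177	80	0.34
PHE	m-85	-65	-85	0.44
PHE	m-30	-65	-30	0.09
TYR	p90	62	90	0.13
TYR	t80	-177	80	0.34
TYR	m-85	-65	-85	0.44
TYR	m-30	-65	-30	0.09
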