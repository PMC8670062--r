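population	super_population	trait	sex_stratum	phenotype_kind	phenotype_value
ASW	AFR	lactase_persistence	combined	prevalence	0.25
ESN	AFR	lactase_persistence	combined	prevalence	0.13
GWD	AFR	lactase_persistence	combined	prevalence	0.430
LWK	AFR	lactase_persistence	combined	prevalence	0.61
MSL	AFR	lactase_persistence	combined	prevalence	0.52
YRI	AFR	lactase_persistence	combined	prevalence	0.13
CLM	AMR	lactase_persistence	combined	prevalence	0.2
MXL	AMR	lactase_persistence	combined	prevalence	0.52
PEL	AMR	lactase_persistence	combined	prevalence	0.06
CDX	EAS	lactase_persistence	combined	prevalence	0.15
CHB	EAS	lactase_persistence	combined	prevalence	0.15
CHS	EAS	lactase_persistence	combined	prevalence	0.15
JPT	EAS	lactase_persistence	combined	prevalence	0.27
KHV	EAS	lactase_persistence	combined	prevalence	0.02
CEU	EUR	lactase_persistence	combined	prevalence	0.87
FIN	EUR	lactase_persistence	combined	prevalence	0.81
GBR	EUR	lactase_persistence	combined	prevalence	0.92
IBS	EUR	lactase_persistence	combined	prevalence	0.71
TSI	EUR	lactase_persistence	combined	prevalence	0.28
BEB	SAS	lactase_persistence	combined	prevalence	0.175
GIH	SAS	lactase_persistence	combined	prevalence	0.39
ITU	SAS	lactase_persistence	combined	prevalence	0.39
PJL	SAS	lactase_persistence	combined	prevalence	0.42
STU	SAS	lactase_persistence	combined	prevalence	0.27
ACB	AFR	melanoma	combined	prevalence	4.2e-5
ASW	AFR	melanoma	combined	prevalence	2.9e-5
ESN	AFR	melanoma	combined	prevalence	5.7e-6
LWK	AFR	melanoma	combined	prevalence	1.4e-5
MSL	AFR	melanoma	combined	prevalence	5.6e-6
YRI	AFR	melanoma	combined	prevalence	5.7e-6
CLM	AMR	melanoma	combined	prevalence	1.08e-4
MXL	AMR	melanoma	combined	prevalence	6.9e-5
PEL	AMR	melanoma	combined	prevalence	8.3e-5
PUR	AMR	melanoma	combined	prevalence	1.11e-4
CDX	EAS	melanoma	combined	prevalence	1.5e-5
CHB	EAS	melanoma	combined	prevalence	1.5e-5
CHS	EAS	melanoma	combined	prevalence	1.5e-5
JPT	EAS	melanoma	combined	prevalence	5.0e-5
KHV	EAS	melanoma	combined	prevalence	4.3e-6
CEU	EUR	melanoma	combined	prevalence	1.3e-3
FIN	EUR	melanoma	combined	prevalence	1.04e-3
GBR	EUR	melanoma	combined	prevalence	9.39e-4
IBS	EUR	melanoma	combined	prevalence	3.92e-4
TSI	EUR	melanoma	combined	prevalence	7.12e-4
BEB	SAS	melanoma	combined	prevalence	6.5e-6
GIH	SAS	melanoma	combined	prevalence	5.4e-6
ITU	SAS	melanoma	combined	prevalence	5.4e-6
PJL	SAS	melanoma	combined	prevalence	4.6e-6
STU	SAS	melanoma	combined	prevalence	1.4e-5
ACB	AFR	multiple_sclerosis	combined	prevalence	1.36e-4
ESN	AFR	multiple_sclerosis	combined	prevalence	3.71e-5
GWD	AFR	multiple_sclerosis	combined	prevalence	3.35e-5
LWK	AFR	multiple_sclerosis	combined	prevalence	3.30e-5
MSL	AFR	multiple_sclerosis	combined	prevalence	2.89e-5
YRI	AFR	multiple_sclerosis	combined	prevalence	3.71e-5
CLM	AMR	multiple_sclerosis	combined	prevalence	5.53e-5
MXL	AMR	multiple_sclerosis	combined	prevalence	1.08e-4
PEL	AMR	multiple_sclerosis	combined	prevalence	6.98e-5
PUR	AMR	multiple_sclerosis	combined	prevalence	1.9e-4
CDX	EAS	multiple_sclerosis	combined	prevalence	7.30e-5
CHB	EAS	multiple_sclerosis	combined	prevalence	7.30e-5
CHS	EAS	multiple_sclerosis	combined	prevalence	7.30e-5
JPT	EAS	multiple_sclerosis	combined	prevalence	3.62e-4
KHV	EAS	multiple_sclerosis	combined	prevalence	4.41e-5
FIN	EUR	multiple_sclerosis	combined	prevalence	1.49e-3
GBR	EUR	multiple_sclerosis	combined	prevalence	1.61e-3
IBS	EUR	multiple_sclerosis	combined	prevalence	9.41e-4
TSI	EUR	multiple_sclerosis	combined	prevalence	1.19e-3
BEB	SAS	multiple_sclerosis	combined	prevalence	1.42e-4
GIH	SAS	multiple_sclerosis	combined	prevalence	1.54e-4
ITU	SAS	multiple_sclerosis	combined	prevalence	1.54e-4
PJL	SAS	multiple_sclerosis	combined	prevalence	1.46e-4
STU	SAS	multiple_sclerosis	combined	prevalence	3.35e-5
ACB	AFR	height	male	quantitative	175.9
ASW	AFR	height	male	quantitative	175.5
ESN	AFR	height	male	quantitative	165.9
GWD	AFR	height	male	quantitative	165.4
LWK	AFR	height	male	quantitative	169.6
MSL	AFR	height	male	quantitative	164.4
YRI	AFR	height	male	quantitative	165.9
CLM	AMR	height	male	quantitative	169.5
MXL	AMR	height	male	quantitative	169.0
PEL	AMR	height	male	quantitative	165.2
PUR	AMR	height	male	quantitative	172.1
CDX	EAS	height	male	quantitative	171.8
CHB	EAS	height	male	quantitative	171.8
CHS	EAS	height	male	quantitative	171.8
JPT	EAS	height	male	quantitative	170.8
KHV	EAS	height	male	quantitative	164.5
CEU	EUR	height	male	quantitative	177.4
FIN	EUR	height	male	quantitative	179.6
GBR	EUR	height	male	quantitative	177.5
IBS	EUR	height	male	quantitative	176.6
TSI	EUR	height	male	quantitative	177.8
BEB	SAS	height	male	quantitative	163.8
GIH	SAS	height	male	quantitative	165.0
ITU	SAS	height	male	quantitative	165.0
PJL	SAS	height	male	quantitative	167.0
STU	SAS	height	male	quantitative	165.7
ACB	AFR	height	female	quantitative	165.3
ASW	AFR	height	female	quantitative	162.6
ESN	AFR	height	female	quantitative	156.3
GWD	AFR	height	female	quantitative	160.9
LWK	AFR	height	female	quantitative	158.2
MSL	AFR	height	female	quantitative	156.6
YRI	AFR	height	female	quantitative	156.3
CLM	AMR	height	female	quantitative	156.95
MXL	AMR	height	female	quantitative	156.9
PEL	AMR	height	female	quantitative	152.9
PUR	AMR	height	female	quantitative	159.2
CDX	EAS	height	female	quantitative	159.7
CHB	EAS	height	female	quantitative	159.7
CHS	EAS	height	female	quantitative	159.7
JPT	EAS	height	female	quantitative	158.3
KHV	EAS	height	female	quantitative	153.6
CEU	EUR	height	female	quantitative	163.3
FIN	EUR	height	female	quantitative	165.9
GBR	EUR	height	female	quantitative	164.4
IBS	EUR	height	female	quantitative	163.4
TSI	EUR	height	female	quantitative	164.6
BEB	SAS	height	female	quantitative	150.8
GIH	SAS	height	female	quantitative	152.6
ITU	SAS	height	female	quantitative	152.6
PJL	SAS	height	female	quantitative	153.8
STU	SAS	height	female	quantitative	154.6
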