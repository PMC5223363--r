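name	network	x	y	z	radius_mm
LPCC	DMN	-8	-56	26	6
RPCC	DMN	6	-52	24	6
LAngular	DMN	-44	-68	36	6
RAngular	DMN	50	-62	32	6
LamPFC	DMN	-2	54	-8	6
LLTC	DMN	-60	-10	-20	6
RLTC	DMN	62	-8	-22	6
RFI	SN	35	24	5	6
LFI	SN	-32	20	6	6
RACC	SN	6	16	42	6
RDLPFC	SN	38	48	26	6
LDLPFC	SN	-38	42	22	6
RSMG	SN	62	-34	40	6
RIPS	DAN	22	-58	54	6
LIPS	DAN	-22	-58	56	6
RpostIPS	DAN	28	-74	34	6
LpostIPS	DAN	-22	-76	34	6
RFEF	DAN	26	-4	52	6
RMTG	DAN	50	-60	-8	6
LMTG	DAN	-48	-66	-4	6
RSP	FPCN	53	-49	47	6
LSP	FPCN	-54	-50	48	6
RMFG	FPCN	44	30	40	6
LMFG	FPCN	-44	28	38	6
RdmPFC	FPCN	4	30	44	6
RdPCC	FPCN	4	-36	44	6
RFP	FPCN	36	58	0	6
LAC	AN	-64	-28	13	6
RAC	AN	60	-24	14	6
LACC	AN	-4	2	44	6
RACC	AN	2	-4	48	6
LantLatSul	AN	-56	0	-2	6
RantLatSul	AN	60	0	2	6
RVC	VN	7	-76	10	6
LVC	VN	-7	-76	10	6
RLGN	VN	22	-26	-6	6
LLGN	VN	-22	-28	-6	6
LMC	MN	-36	-25	57	6
RMC	MN	40	-26	56	6
SMA	MN	-2	-20	54	6
LInsula	MN	-36	-18	16	6
RInsula	MN	38	-16	16	6
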