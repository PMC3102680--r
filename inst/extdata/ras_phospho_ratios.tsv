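peptide_id	protein	gene	sequence	sites	3KTR/3KT	A549/3KT	H322/3KT	H1299/3KT
P46379_S113	P46379	BAT3	APPQTHLPSGASSGTGSASATHGGGsPPGTR	S113	1.718	1.680	2.423	0.806
P46379_S104	P46379	BAT3	APPQTHLPSGASSGTGsASATHGGGSPPGTR	S104	1.717	1.664	2.400	0.776
P46379_T108	P46379	BAT3	APPQTHLPSGASSGTGSASAtHGGGSPPGTR	T108	1.715	1.679	2.420	0.803
Q9NYF8_S222	Q9NYF8	BCLAF1	SSATSGDIWPGLSAYDNsPR	S222	1.104	1.612	1.176	0.688
Q9NYF8_S217	Q9NYF8	BCLAF1	SSATSGDIWPGLsAYDNSPR	S217	1.098	1.612	1.176	0.688
Q8WX92_T564	Q8WX92	COBRA1	KPSPAQAAEtPALELPLPSVPAPAPL	T564	1.593	1.540	1.829	0.514
Q8WX92_S557	Q8WX92	COBRA1	KPsPAQAAETPALELPLPSVPAPAPL	S557	1.589	1.531	1.827	0.477
Q8N707_T364	Q8N707	CTTN	TQtPPVSPAPQPTEER	T364	1.065	1.052	1.236	-1.680
Q96TA1_S679	Q96TA1	FAM129B	AAPEASsPPASPLQHLLPGK	S679	2.107	1.752	1.556	-9999
P02545_S392	P02545	LMNA	LSPsPTSQR	S392	1.737	1.102	1.475	0.977
P02545_S390	P02545	LMNA	LsPSPTSQR	S390	1.193	1.098	1.084	0.975
P28482_Y187	P28482	MAPK1	VADPDHDHTGFLTEyVATR	Y187	1.946	1.024	1.599	-1.308
Q8TDZ2_S829	Q8TDZ2	MICAL1	LSsPERQR	S829	1.737	1.108	1.220	0.972
Q8WUF5_S113	Q8WUF5	PPP1R13L	SESAPTLHPYSPLsPK	S113	1.218	1.235	1.688	0.532
Q9UQ35_T2409	Q9UQ35	SRRM2	SRtPPSAPSQSR	T2409	1.361	1.838	1.460	0.623
Q8IZP0_S225	Q8IZP0	ABI1	LGSQHsPGR	S225	-1.184	-1.181	-1.932	-0.669
Q9BZZ5_S464	Q9BZZ5	API5	RASEDTTSGsPPKK	S464	-1.704	-3.756	-3.442	0.429
Q8WX93_S880	Q8WX93	PALLD	sPSGHPHVR	S880	-1.017	-1.676	-1.510	-0.586
Q8WWA1_S153	Q8WWA1	TMEM40	RGsDPASGEVEASQLR	S153	-1.293	-5.644	-2.08	-9999
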