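patient_id	gender	model_id	subtype	disease_status	sample_origin	wes_available
P1	F	VFN-D3	DLBCL	Dg	LN	Yes
P2	M	VFN-D6	DLBCL	Dg	LN	Yes
P3	M	VFN-D1	DLBCL	R/R	LN	Yes
P4	M	VFN-D4	DLBCL	R/R	EN	Yes
P5	F	VFN-D5	DLBCL	R/R	LN	Yes
P6	M	VFN-D12	tDLBCL	Dg	LN	No
P7	F	VFN-D20	DLBCL	R/R	LN	Yes
P8	M	VFN-B3	BL	R/R	EN	Yes
P9	M	VFN-M5R1	MCL	R/R	LN	Yes
P10	F	VFN-M1	MCL	R/R	LN	Yes
P11	M	VFN-T3	AITL	R/R	LN	Yes
P12	F	VFN-T7	AITL	R/R	LN	No
P13	F	VFN-T6	PTCL-NOS	R/R	LN	Yes
P14	M	VFN-T5	ALCL	Dg	LN	Yes
P15	M	VFN-T4	ALCL	Dg	LN	Yes
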