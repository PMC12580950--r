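panel	gene_id
fatty_acid_biosynthesis	SAST
fatty_acid_biosynthesis	OXSM
fatty_acid_biosynthesis	IQCAL
fatty_acid_biosynthesis	IQCA1
fatty_acid_biosynthesis	FAS
fatty_acid_biosynthesis	FABD
fatty_acid_biosynthesis	CCD57
fatty_acid_biosynthesis	ACSL1
fatty_acid_biosynthesis	ACSL3
fatty_acid_biosynthesis	ACSL4
fatty_acid_biosynthesis	ACSL5
fatty_acid_biosynthesis	ACSL6
fatty_acid_biosynthesis	ACBG1
fatty_acid_biosynthesis	ACBG2
fatty_acid_biosynthesis	ACAC
fatty_acid_degradation	THIM
fatty_acid_degradation	THIL
fatty_acid_degradation	THIK
fatty_acid_degradation	THIC
fatty_acid_degradation	SPAT9
fatty_acid_degradation	GNB1L
fatty_acid_degradation	GCDH
fatty_acid_degradation	ECI
fatty_acid_degradation	ECHP
fatty_acid_degradation	ECHM
fatty_acid_degradation	ECHA
fatty_acid_degradation	ECHB
fatty_acid_degradation	CPT2
fatty_acid_degradation	CPT1A
fatty_acid_degradation	CPT1B
fatty_acid_degradation	CPT1C
fatty_acid_degradation	CP4CA
fatty_acid_degradation	CP4AO
fatty_acid_degradation	CP4AB
fatty_acid_degradation	AL9A1
fatty_acid_degradation	AL7A1
fatty_acid_degradation	AL3A2
fatty_acid_degradation	ADH
fatty_acid_degradation	ACSL1
fatty_acid_degradation	ACSL3
fatty_acid_degradation	ACSL4
fatty_acid_degradation	ACSL5
fatty_acid_degradation	ACSL6
fatty_acid_degradation	ACOXL
fatty_acid_degradation	ACOX1
fatty_acid_degradation	ACOX3
fatty_acid_degradation	ACDSB
fatty_acid_degradation	ACBG2
fatty_acid_degradation	ACBG1
fatty_acid_degradation	ACADV
fatty_acid_degradation	ACADS
fatty_acid_degradation	A16A1
fatty_acid_elongation	THIM
fatty_acid_elongation	TECRL
fatty_acid_elongation	TECR
fatty_acid_elongation	SLMAP
fatty_acid_elongation	PPT1
fatty_acid_elongation	PPT2
fatty_acid_elongation	MECR
fatty_acid_elongation	HSDL1
fatty_acid_elongation	HACD
fatty_acid_elongation	ELOV
fatty_acid_elongation	ECHM
fatty_acid_elongation	ECHB
fatty_acid_elongation	ECHA
fatty_acid_elongation	DHB12
fatty_acid_elongation	BACH
fatty_acid_elongation	ACOT1
fatty_acid_elongation	ACOT2
fatty_acid_elongation	ACOT4
muscle_fiber_structure	TPM1
muscle_fiber_structure	MYH1
muscle_fiber_structure	MYL6B
muscle_fiber_structure	TNNI1
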