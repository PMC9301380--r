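sample_id	junction	junction_aa	v_call	d_call	j_call	duplicate_count
HD01_CD27pos_r1	TGTGCCTGTGACACCCTGGGGGATACGGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2*01	TRDD3*01	TRDJ1*01	40
HD01_CD27pos_r1	TGTGCCTGTGACACCGGCCTGGGGGATACGGATAAACTCATCTTT	CACDTGLGDTDKLIF	TRDV2*01	TRDD3*01	TRDJ1*01	12
HD01_CD27pos_r1	TGTGCCTGTGACACCGAAGGTACTCCAACTCTCCTCATCTTT	CACDTEGTPTLLIF	TRDV2*01	NA	TRDJ1*01	5
HD01_CD27pos_r1	TGTGCCTGTGACACCAAAGATAAACTCATCTTT	CACDTKDKLIF	TRDV2*01	NA	TRDJ1*01	1
HD01_CD27pos_r2	TGTGCCTGTGACACCCTGGGGGATACGGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2*01	TRDD3*01	TRDJ1*01	35
HD01_CD27pos_r2	TGTGCCTGTGACACCGGCCTGGGGGATACGGATAAACTCATCTTT	CACDTGLGDTDKLIF	TRDV2*01	TRDD3*01	TRDJ1*01	9
HD02_CD27pos_r1	TGTGCCTGTGACACCCTGGGGGATACGGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2*01	TRDD3*01	TRDJ1*01	22
HD02_CD27pos_r1	TGTGCCTGTGACACCGAAGGTACTCCAACTCTCCTCATCTTT	CACDTEGTPTLLIF	TRDV2*01	NA	TRDJ1*01	7
HD02_CD27pos_r2	TGTGCCTGTGACACCCTGGGGGATACGGATAAACTCATCTTT	CACDTLGDTDKLIF	TRDV2*01	TRDD3*01	TRDJ1*01	18
HD02_CD27pos_r2	TGTGCCTGTGACACCGAAGGTACTCCAACTCTCCTCATCTTT	CACDTEGTPTLLIF	TRDV2*01	NA	TRDJ1*01	6
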