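name	locus	tag_depth	strand	size
ncRNA_01	chr2R_4733783_4733804	5027	+	21
ncRNA_02	chr2R_9632216_9632238	6051	-	22
ncRNA_03	chr2R_13693470_13693490	5460	-	20
ncRNA_04	chr2R_19535102_19535122	5460	-	20
ncRNA_06	chrX_11524384_11524406	5685	+	22
ncRNA_07	chrX_12399632_12399653	5697	-	21
ncRNA_08	chrX_19880356_19880381	6749	+	25
ncRNA_05	chrX_3721726_3721755	4733	+	29
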