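name	formula	charge	dGf0_kJ_mol	ion_size_A	phase
H2O	H2O	0	-237.183	NA	liquid
H+	H	1	0	9.0	aqueous
OH-	HO	-1	-157.297	3.5	aqueous
O2	O2	0	16.544	NA	aqueous
HCO3-	HCO3	-1	-586.940	4.0	aqueous
CO2	CO2	0	-385.974	NA	aqueous
CO3-2	CO3	-2	-527.983	4.5	aqueous
SO4-2	SO4	-2	-744.459	4.0	aqueous
HS-	HS	-1	11.966	3.5	aqueous
H2S	H2S	0	-27.920	NA	aqueous
S2O3-2	S2O3	-2	-522.500	4.0	aqueous
NH4+	NH4	1	-79.454	2.5	aqueous
Na+	Na	1	-261.881	4.0	aqueous
Cl-	Cl	-1	-131.290	3.0	aqueous
CH4	CH4	0	-34.451	NA	aqueous
glucose	C6H12O6	0	-915.900	NA	aqueous
acetate	C2H3O2	-1	-369.322	4.5	aqueous
methanol	CH4O	0	-175.937	NA	aqueous
formate	CHO2	-1	-350.879	3.5	aqueous
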