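compound	formula	charge	concentration
glucose	C6H12O6	0	4.0e-6
pyruvate	C3H3O3	-1	4.0e-6
acetate	C2H3O2	-1	4.0e-6
succinate	C4H4O4	-2	2.0e-6
glycine	C2H5NO2	0	2.0e-6
alanine	C3H7NO2	0	2.0e-6
leucine	C6H13NO2	0	2.0e-6
methionine	C5H11NO2S	0	1.0e-6
glycerol	C3H8O3	0	2.0e-6
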