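parameter	value	units	note
intercept	60.3	kJ (mol C)-1	linear NOSC-to-Gibbs-energy relation for the organic carbon oxidation half reaction (LaRowe & Van Cappellen 2011)
slope	-28.5	kJ (mol C)-1 per NOSC unit	same relation; oxidation half reaction written to bicarbonate
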