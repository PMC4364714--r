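id	sex	age_group	ganglionic_fraction	megacolon
A01	M	weaning	62.5	TRUE
A02	M	weaning	71.0	TRUE
A03	M	weaning	78.3	TRUE
A04	M	weaning	83.6	TRUE
A05	F	weaning	80.9	TRUE
A06	M	weaning	77.1	FALSE
A07	M	weaning	82.4	FALSE
A08	F	weaning	86.2	FALSE
A09	F	weaning	91.5	FALSE
A10	F	weaning	95.0	FALSE
A11	M	weaning	88.7	FALSE
A12	F	weaning	97.8	FALSE
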