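# Pseudoatom / wildcard proton nomenclature map. 'pseudo' names (and trailing
# */#/% wildcards reduced to 'stem*') expand to explicit proton groups.
pseudo	expansion
H5'*	H5',H5''
H2'*	H2',H2''
H5'1	H5'
H5'2	H5''
H2'1	H2'
H2'2	H2''
M7	H71,H72,H73
H7*	H71,H72,H73
Q7	H71,H72,H73
Q2	H21,H22
Q4	H41,H42
Q6	H61,H62
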