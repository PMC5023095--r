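marker	haplogroup	parent	mutation_kind	ancestral	derived
M175	O	root	deletion	TTCTC	del
RPS4Y	C	root	substitution	C	T
M231	N	root	substitution	G	A
M174	D	root	substitution	T	C
M304	J	root	substitution	T	G
M242	Q	root	substitution	C	T
M207	R	root	substitution	A	G
M173	R1	R	substitution	A	C
M17	R1a1a	R1	deletion	G	del
M343	R1b	R1	substitution	C	A
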