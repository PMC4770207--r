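# RNA/RNA nearest-neighbor stacking parameters, Watson-Crick set
# (Xia et al. 1998), 1 M NaCl reference state.
# stack: 5'->3' dinucleotide on the strand whose Tm is computed, paired with
# its perfect complement; parameters are symmetric under reverse complement.
# dH in kcal/mol, dS in cal/(mol*K).
# 'init' is the duplex initiation term, 'term_AU' the per-end penalty for a
# terminal A-U (or U-A) pair.
stack	dH	dS
AA	-6.82	-19.0
UU	-6.82	-19.0
AU	-9.38	-26.7
UA	-7.69	-20.5
CU	-10.48	-27.1
AG	-10.48	-27.1
CA	-10.44	-26.9
UG	-10.44	-26.9
GU	-11.40	-29.5
AC	-11.40	-29.5
GA	-12.44	-32.5
UC	-12.44	-32.5
CG	-10.64	-26.7
GG	-13.39	-32.7
CC	-13.39	-32.7
GC	-14.88	-36.9
init	3.61	-1.5
term_AU	3.72	10.5
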