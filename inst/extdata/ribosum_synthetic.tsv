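# SYNTHETIC RIBOSUM-style base-pair substitution matrix.
# Not estimated from ribosomal alignments: a deterministic stand-in with the
# qualitative log-odds structure of the RIBOSUM family (conserved canonical
# pairs positive, compensatory double substitutions highest, non-canonical
# dinucleotides negative).  Generated by phylocofold::synthetic_ribosum().
# Substitute a genuine RIBOSUM matrix in the same TSV layout for production.
	AA	AC	AG	AU	CA	CC	CG	CU	GA	GC	GG	GU	UA	UC	UG	UU
AA	-2.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0
AC	-4.0	-2.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0
AG	-4.0	-4.0	-2.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0
AU	-4.0	-4.0	-4.0	2.0	-4.0	-4.0	3.5	-4.0	-4.0	3.5	-4.0	1.2	3.5	-4.0	3.5	-4.0
CA	-4.0	-4.0	-4.0	-4.0	-2.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0
CC	-4.0	-4.0	-4.0	-4.0	-4.0	-2.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0
CG	-4.0	-4.0	-4.0	3.5	-4.0	-4.0	2.0	-4.0	-4.0	3.5	-4.0	3.5	3.5	-4.0	1.2	-4.0
CU	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-2.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0
GA	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-2.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0
GC	-4.0	-4.0	-4.0	3.5	-4.0	-4.0	3.5	-4.0	-4.0	2.0	-4.0	1.2	3.5	-4.0	3.5	-4.0
GG	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-2.0	-4.0	-4.0	-4.0	-4.0	-4.0
GU	-4.0	-4.0	-4.0	1.2	-4.0	-4.0	3.5	-4.0	-4.0	1.2	-4.0	2.0	3.5	-4.0	3.5	-4.0
UA	-4.0	-4.0	-4.0	3.5	-4.0	-4.0	3.5	-4.0	-4.0	3.5	-4.0	3.5	2.0	-4.0	1.2	-4.0
UC	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-2.0	-4.0	-4.0
UG	-4.0	-4.0	-4.0	3.5	-4.0	-4.0	1.2	-4.0	-4.0	3.5	-4.0	3.5	1.2	-4.0	2.0	-4.0
UU	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-4.0	-2.0
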