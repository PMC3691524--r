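# simplified nearest-neighbour energy model (kcal/mol)
hairpin_a 5.6
hairpin_b 1.7
hairpin_short 6
interior_a 1.1
interior_b 1.1
Ma 3.4
Mb 0.4
Mc 0.1
max_interior 30
# stacking: rows outer pair, cols inner pair; order AU UA CG GC GU UG
stack
-0.9 -1.1 -2.2 -2.1 -0.6 -1.4
-1.3 -0.9 -2.4 -2.1 -1 -1.3
-2.1 -2.1 -3.3 -2.4 -1.4 -2.1
-2.4 -2.2 -3.4 -3.3 -1.5 -2.5
-1.3 -1.4 -2.5 -2.1 -0.5 1.3
-1 -0.6 -1.5 -1.4 0.3 -0.5
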