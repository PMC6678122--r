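# Nearest-neighbour stacking free energies (kcal/mol) for the bundled
# single-stem folding engine and the target-duplex energy model.
# Row = outer (5'-proximal) pair, column = inner pair stacked on it, read
# 5'->3' on the top strand. Pair labels give top:bottom strand bases.
# Watson-Crick values follow the familiar Turner-style ordering (GC-rich
# stacks strongest); every stack containing a G:U wobble is constructed to
# be strictly weaker than the same stack with that wobble replaced by its
# Watson-Crick counterpart (G:U -> G:C, U:G -> U:A), so replacing a WC pair
# by a wobble can never strengthen a duplex.
pair	AU	UA	GC	CG	GU	UG
AU	-0.9	-1.1	-2.1	-2.2	-0.9	-0.3
UA	-1.3	-0.9	-2.4	-2.1	-1.2	-0.1
GC	-2.2	-2.1	-3.3	-3.4	-2.1	-1.3
CG	-2.1	-2.4	-3.4	-3.3	-2.2	-1.6
GU	-1.0	-0.9	-2.1	-2.2	-0.9	-0.1
UG	-0.5	-0.1	-1.6	-1.3	-0.4	-0.1
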