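# Published miRNAs significantly differentially expressed in BOTH successive
# phase comparisons of the Pongamia seed study, with their signed log2 fold
# changes (phase II vs I, phase III vs II). `group` records whether the two
# changes had the same or opposite direction in the source summary.
mirna_id	origin	log2fc_II_I	log2fc_III_II	group
mpi-miR156f-5p	conserved	7.65	1.74	same
mpi-miR482a-3p	conserved	1.58	1.49	same
mpi-nmiR0004-3p	novel	1.07	1.28	same
mpi-nmiR0083-3p	novel	9.71	2.28	same
mpi-nmiR0119-5p	novel	7.92	1.26	same
mpi-miR156a-3p	conserved	-1.39	-1.19	same
mpi-miR164a-5p	conserved	-2.37	-1.67	same
mpi-miR166a-5p	conserved	-1.03	-1.22	same
mpi-miR166k-5p	conserved	-3.37	-2.32	same
mpi-miR171j-5p	conserved	-2.83	-3.43	same
mpi-miR393b-5p	conserved	-1.31	-1.64	same
mpi-miR399a-3p	conserved	-1.65	-1.24	same
mpi-miR399b-3p	conserved	-1.35	-2.25	same
mpi-miR156c-5p	conserved	2.01	-2.16	opposite
mpi-miR168d-3p	conserved	8.49	-8.49	opposite
mpi-miR171b-3p	conserved	2.22	-1.02	opposite
mpi-miR398c-3p	conserved	2.25	-2.21	opposite
mpi-miR398f-3p	conserved	4.52	-4.40	opposite
mpi-miR408a-3p	conserved	2.56	-1.91	opposite
mpi-miR408b-3p	conserved	3.62	-1.66	opposite
mpi-miR408d-3p	conserved	3.75	-1.28	opposite
mpi-miR4403-5p	conserved	1.39	-2.06	opposite
mpi-miR5037	conserved	7.32	-7.32	opposite
mpi-nmiR0028-3p	novel	2.44	-2.75	opposite
mpi-nmiR0034-3p	novel	1.28	-1.73	opposite
mpi-nmiR0050-5p	novel	8.50	-8.50	opposite
mpi-nmiR0072-5p	novel	1.25	-3.06	opposite
mpi-nmiR0103-5p	novel	9.63	-9.63	opposite
mpi-miR396c-3p	conserved	-2.50	1.13	opposite
mpi-miR396e-5p	conserved	-8.57	7.88	opposite
mpi-miR399d-3p	conserved	-10.94	7.99	opposite
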