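# Published per-library summary statistics of a nine-library small-RNA
# profiling experiment in developing Pongamia (Millettia pinnata) seeds:
# three developmental phases (I embryogenesis, II seed filling,
# III desiccation) x three biological replicates. conserved_mirna_reads is
# the number of clean reads perfectly matching known plant mature miRNAs.
library	phase	raw_reads	clean_reads	unique_tags	conserved_mirna_reads	n_conserved_mirnas	n_novel_mirnas
MpSI-1	I	31711290	21400622	2757270	1723573	174	87
MpSI-2	I	31959711	21401693	2876894	1519586	172	82
MpSI-3	I	31763941	21217533	2882107	1115971	168	68
MpSII-1	II	27733326	17612476	3066337	777660	157	70
MpSII-2	II	33988872	21414373	3427062	823736	165	64
MpSII-3	II	31143787	19377920	2942567	1207854	183	83
MpSIII-1	III	31167480	20039686	2593393	1230083	163	97
MpSIII-2	III	32681945	20872904	2774500	1206643	162	94
MpSIII-3	III	31100220	19792612	2443701	1271965	160	93
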