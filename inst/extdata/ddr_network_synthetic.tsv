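# Miniature miRNA-DDR regulatory network edge list (synthetic stand-in).
# The first block lists interactions documented in the primary literature
# (miR-24 -> H2AX, miR-421 -> ATM, miR-146 -> BRCA1, miR-151 -> ARHGDIA,
# RAD17 <- {miR-421, miR-505*, miR-324}, RAD9A <- {let-7a*, miR-320});
# the remaining rows are synthetic filler so the file exercises every
# pathway class. Not the full curated 142-edge network.
mirna	gene	pathway	evidence
miR-24	H2AX	DDS	literature
miR-421	ATM	DDS	literature
miR-146	BRCA1	HR	literature
miR-151	ARHGDIA	other	literature
miR-421	RAD17	DDS	literature
miR-505*	RAD17	DDS	literature
miR-324	RAD17	DDS	literature
let-7a*	RAD9A	DDS	literature
miR-320	RAD9A	DDS	literature
miR-301b	ATR	DDS	synthetic
miR-502	CHEK1	DDS	synthetic
miR-193a	RAD51	HR	synthetic
miR-146a*	BRCA1	HR	synthetic
miR-29	TP53	DDS	synthetic
miR-16	MDM2	DDS	synthetic
miR-34	SIRT1	DDS	synthetic
miR-21	MSH2	MMR	synthetic
miR-373	ERCC1	NER	synthetic
miR-96	OGG1	BER	synthetic
miR-182	XRCC4	NHEJ	synthetic
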