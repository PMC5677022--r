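# The default 10-miRNA instability signature: direction "+" scores a point
# when expression is above the cohort median, "-" when below.
mirna	direction
miR-151	+
miR-301b	+
miR-505*	+
miR-324	+
miR-502	+
miR-421	+
let-7a*	-
miR-320	-
miR-146a*	-
miR-193a	-
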