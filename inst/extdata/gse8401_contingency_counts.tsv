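# Published 2x2 contingency counts of acid-modulated B16-BL6 genes
# (two-fold threshold) against the expression classes of the GSE8401
# melanoma contrasts (Mets = metastasized tumor cells, CTC =
# circulating tumor cells). class_size is the size of the signature
# class; up/down are counts of acid-up- and acid-down-regulated genes
# falling in that class, for each acidic condition vs control pH 7.4.
contrast	condition	class	class_size	up	down
Mets vs primary	pH6.8	high	2193	119	68
Mets vs primary	pH6.8	low	333	14	10
Mets vs primary	pH5.9	high	2193	71	44
Mets vs primary	pH5.9	low	333	11	8
CTC vs primary	pH6.8	high	1011	71	43
CTC vs primary	pH6.8	low	10541	822	334
CTC vs primary	pH5.9	high	1011	47	30
CTC vs primary	pH5.9	low	10541	533	233
CTC vs Mets	pH6.8	high	649	53	31
CTC vs Mets	pH6.8	low	12203	928	377
CTC vs Mets	pH5.9	high	649	40	26
CTC vs Mets	pH5.9	low	12203	592	256
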