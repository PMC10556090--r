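# Example reported-signature gene list (one symbol per line, '#' = comment).
# Cancer-related genes of a widely used 21-gene recurrence-score panel;
# shipped as an editable example of the gene-list file format.
KI67
MKI67
AURKA
BIRC5
CCNB1
MYBL2
MMP11
CTSL2
GRB7
ERBB2
ESR1
PGR
BCL2
SCUBE2
GSTM1
BAG1
CD68
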