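# Example reported-signature gene list: a small proliferation/cell-cycle
# module of the kind random signatures tend to correlate with.
MKI67
PCNA
TOP2A
CCNB1
CCNE1
CDK1
BUB1
AURKB
PLK1
RRM2
TYMS
FOXM1
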