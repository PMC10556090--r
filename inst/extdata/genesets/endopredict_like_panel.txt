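# Example reported-signature gene list: the 8 informative genes of a
# published endocrine-response panel; editable example of the file format.
BIRC5
UBE2C
DHCR7
RBBP8
IL6ST
AZGP1
MGP
STC2
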