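NFE2L2
NQO1
GCLC
GCLM
HMOX1
TXNRD1
SRXN1
GSR
ME1
AKR1B10
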