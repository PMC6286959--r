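TP53
CDKN1A
MDM2
BAX
GADD45A
BBC3
SESN1
RRM2B
TIGAR
ZMAT3
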