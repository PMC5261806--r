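JNB
FJQ
QFP
PPN
NJF
JPFQ
QBNF
FQBP
BFFB
NJBN
JPQNP
BQPBB
PFJNQ
NQNBJ
FPJQJ
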