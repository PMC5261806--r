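XLJ
NXQ
LQP
PNN
JPL
QJNX
PQLQ
XPJL
LNQN
NJXJ
JNPXP
LXJQJ
PLXNQ
QQLPN
XLJPX
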