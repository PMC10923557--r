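code,meaning,attested
W,widowed at marriage,yes
Z,stillborn,yes
2,twin,yes
3,triplet,no
P,pauper,no
O,posthumous birth,no
I,illegitimate,no
D,religious dissenter,no
S,name suffix senior/elder,no
J,name suffix junior/younger,no
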