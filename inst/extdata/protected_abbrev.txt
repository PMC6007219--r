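# abbreviations that never end a sentence
fig
figs
e.g
i.e
et al
al
vs
subsp
spp
sp
var
cf
ca
approx
st
no
etc
ref
refs
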