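term
dressing
bandage
stocking
garment
hosiery
catheter
lancet
test strip
needle
syringe
wipe
dietary supplement drink
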