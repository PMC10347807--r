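code,label
H3...,chronic obstructive pulmonary disease
H36..,mild chronic obstructive pulmonary disease
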