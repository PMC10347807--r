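code,label
K05..,chronic kidney disease
1Z12.,chronic kidney disease stage 3
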