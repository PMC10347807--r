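code,label
C10..,diabetes mellitus
C10F.,type 2 diabetes mellitus
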