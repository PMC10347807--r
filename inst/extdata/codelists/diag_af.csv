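code,label
G573.,atrial fibrillation and flutter
G5730,atrial fibrillation
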