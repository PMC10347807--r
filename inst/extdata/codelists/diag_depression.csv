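code,label
E112.,single major depressive episode
E2B..,depressive disorder NEC
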