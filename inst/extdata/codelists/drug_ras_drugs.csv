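code,label
ramipril,ACE inhibitor
lisinopril,ACE inhibitor
perindopril,ACE inhibitor
losartan,angiotensin receptor blocker
candesartan,angiotensin receptor blocker
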