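code,label
codeine,opioid analgesic
co-codamol,opioid combination analgesic
tramadol,opioid analgesic
morphine,opioid analgesic
buprenorphine,opioid analgesic
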