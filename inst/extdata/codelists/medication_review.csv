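code,label,flags
8B3V.,medication review,
8B3x.,medication review done by pharmacist,
8B314,medication review without patient,
8B3R.,medication review of medical notes,
8BM19,medication review due,
8B3h.,medication review done by nurse,
66YV.,warfarin monitoring medication review,conservative_excluded
8B3S.,asthma medication review,conservative_excluded
8BIV.,lithium medication review,conservative_excluded
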