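formulation_class,default_days,cap_days
tablet,28,183
capsule,28,183
inhaler,28,183
cream,28,183
ointment,28,183
drops,28,183
injection,28,183
patch,28,183
solution,28,183
sachet,28,183
suppository,28,183
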