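code,label
warfarin,vitamin K antagonist
apixaban,direct oral anticoagulant
rivaroxaban,direct oral anticoagulant
edoxaban,direct oral anticoagulant
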