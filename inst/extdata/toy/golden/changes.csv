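patient_id,review_date,stopped,started,continued,count_before,count_after,delta,excluded_reason
P01,2019-02-01,omeprazole|capsule,aspirin|tablet,atorvastatin|tablet,2,2,0,none
P02,2019-03-15,bendroflumethiazide|tablet;warfarin|tablet,apixaban|tablet,simvastatin|tablet,3,2,-1,none
P06,2019-02-10,,,colecalciferol|tablet,1,1,0,insufficient_followup
P09,2019-04-02,ramipril|tablet,atorvastatin|tablet,amlodipine|tablet;metformin|tablet,3,3,0,none
P10,2019-08-20,,paracetamol|tablet,,0,1,1,no_prescriptions_before
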