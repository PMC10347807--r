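patient_id,medicine,start_date,end_date,source_repeat
P01,aspirin|tablet,2019-02-01,2019-04-25,true
P01,atorvastatin|tablet,2018-12-15,2019-03-04,true
P01,codeine|tablet,2018-05-01,2018-05-28,false
P01,omeprazole|capsule,2018-12-20,2019-01-16,true
P02,apixaban|tablet,2019-03-20,2019-04-16,true
P02,bendroflumethiazide|tablet,2018-12-28,2019-01-24,true
P02,simvastatin|tablet,2018-12-01,2019-05-20,true
P02,warfarin|tablet,2018-11-15,2019-02-06,true
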