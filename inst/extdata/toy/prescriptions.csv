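patient_id,issue_date,substance,formulation,bnf_chapter,bnf_paragraph,quantity,daily_dose,repeat_flag
P01,2018-12-15,atorvastatin,tablet,2,2.12,56,2,true
P01,2019-01-10,atorvastatin,tablet,2,2.12,56,2,true
P01,2019-02-05,atorvastatin,tablet,2,2.12,56,2,true
P01,2018-12-20,omeprazole,capsule,1,1.3.5,28,1,true
P01,2019-02-01,aspirin,tablet,2,2.9,84,1,true
P01,2018-05-01,codeine,tablet,4,4.7.2,56,2,false
P02,2018-12-01,simvastatin,tablet,2,2.12,90,1,true
P02,2019-02-20,simvastatin,tablet,2,2.12,90,1,true
P02,2018-11-15,warfarin,tablet,2,2.8.2,84,1,true
P02,2018-12-28,bendroflumethiazide,tablet,2,2.2.1,28,1,true
P02,2019-03-20,apixaban,tablet,2,2.8.2,56,2,true
P06,2018-12-10,colecalciferol,tablet,9,9.6.4,112,1,true
P07,2018-12-01,ferrous fumarate,tablet,9,9.1.1,60,2,true
P07,2018-12-20,levothyroxine,tablet,6,6.2.1,28,1,true
P08,2018-12-25,absorbent dressing,dressing,,,1,,false
P08,2018-10-01,aspirin,tablet,2,2.9,28,1,true
P09,2018-12-15,metformin,tablet,6,6.1.2,112,2,true
P09,2019-04-05,metformin,tablet,6,6.1.2,112,2,true
P09,2018-12-01,ramipril,tablet,2,2.5.5,28,1,true
P09,2018-12-29,ramipril,tablet,2,2.5.5,28,1,true
P09,2019-01-01,amlodipine,tablet,2,2.6.2,28,1,true
P09,2019-01-27,amlodipine,tablet,2,2.6.2,28,1,true
P09,2019-02-22,amlodipine,tablet,2,2.6.2,28,1,true
P09,2019-03-20,amlodipine,tablet,2,2.6.2,28,1,true
P09,2019-04-10,atorvastatin,tablet,2,2.12,28,1,true
P10,2018-12-20,aspirin,tablet,2,2.9,28,1,true
P10,2019-08-25,paracetamol,tablet,4,4.7.1,56,2,true
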