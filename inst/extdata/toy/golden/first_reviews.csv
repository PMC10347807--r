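patient_id,review_date,code,consultation_type,staff_role,conservative_eligible
P01,2019-02-01,8B3V.,face_to_face,gp,true
P02,2019-03-15,8B3x.,telephone,pharmacist,true
P06,2019-02-10,8B3S.,face_to_face,nurse,false
P09,2019-04-02,8B314,other,admin,false
P10,2019-08-20,8B3V.,face_to_face,gp,true
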