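patient_id,event_date,code,consultation_type,staff_role
P01,2019-02-01,8B3V.,face_to_face,gp
P01,2019-01-15,G20..,face_to_face,gp
P02,2019-03-15,8B3x.,telephone,pharmacist
P02,2018-05-20,8B3V.,face_to_face,gp
P06,2019-02-10,8B3S.,face_to_face,nurse
P06,2015-03-01,H3...,other,gp
P07,2019-01-01,G573.,other,gp
P09,2019-04-02,8B314,other,admin
P09,2019-07-10,8B3V.,face_to_face,gp
P10,2019-08-20,8B3V.,face_to_face,gp
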