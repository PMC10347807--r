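patient_id,review_date,code,consultation_type,staff_role
P01,2019-02-01,8B3V.,face_to_face,gp
P02,2019-03-15,8B3x.,telephone,pharmacist
P09,2019-07-10,8B3V.,face_to_face,gp
P10,2019-08-20,8B3V.,face_to_face,gp
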