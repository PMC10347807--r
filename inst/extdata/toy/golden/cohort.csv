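patient_id,baseline_count,baseline_count_band,prior_year_review,diag_af,diag_copd,diag_hypertension,drug_ras_drugs,drug_statins,drug_oral_anticoagulants,drug_opioids,exit_date,event,time_days
P01,2,2-4,false,false,false,false,false,true,false,false,2019-02-01,true,31
P02,3,2-4,true,false,false,false,false,true,true,false,2019-03-15,true,73
P06,1,1,false,false,true,false,false,false,false,false,2019-02-10,true,40
P07,1,1,false,true,false,false,false,false,false,false,2019-03-01,false,59
P09,3,2-4,false,false,false,false,true,false,false,false,2019-04-02,true,91
P10,1,1,false,false,false,false,false,false,false,false,2019-08-20,true,231
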