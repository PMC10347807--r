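stage,count
total,10
excluded_age,1
excluded_sex,1
excluded_uts,1
excluded_not_active,0
eligible,7
excluded_no_ongoing,1
study_population,6
events,5
censored,1
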