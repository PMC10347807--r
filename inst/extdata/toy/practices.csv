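practice_id,region,last_collection_date,townsend_quintile
PRAC1,scotland,2019-12-31,3
PRAC2,wales,2019-12-31,2
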