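patient_id,sex,birth_year,practice_id,registration_date,uts_date,transfer_out_date,death_date,care_home,ethnicity,townsend_quintile,person_level_townsend
P01,female,1940,PRAC1,2000-01-01,2000-01-01,,,false,white,2,true
P02,male,1950,PRAC1,2005-06-15,2005-06-15,,,true,,,false
P03,female,1955,PRAC1,2010-01-01,2010-01-01,,,false,white,1,true
P04,,1940,PRAC1,2000-01-01,2000-01-01,,,false,,,false
P05,female,1935,PRAC1,2000-01-01,2018-06-01,,,false,white,3,true
P06,male,1945,PRAC1,1999-03-01,1999-03-01,,2019-05-10,false,,,false
P07,female,1948,PRAC1,2001-01-01,2001-01-01,2019-03-01,,false,white,4,true
P08,male,1938,PRAC1,2002-01-01,2002-01-01,,,false,white,5,true
P09,female,1942,PRAC2,2003-01-01,2003-01-01,,,false,asian,1,true
P10,male,1946,PRAC2,2004-01-01,2004-01-01,,,false,white,,false
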