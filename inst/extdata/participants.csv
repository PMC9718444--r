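participant_id,age,gender,period,day_type,urban,diary_date,weight
p01,34,female,during,weekday,TRUE,2021-08-05,1
p02,7,male,after,weekend,FALSE,2021-08-14,1
p03,71,female,during,weekend,TRUE,2021-08-07,1
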