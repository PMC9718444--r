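participant_id,contact_age_lo,contact_age_hi,physical,setting
p01,30,39,FALSE,work
p01,5,5,TRUE,home
p02,8,8,TRUE,school
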