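study_id,r11,n1,r00,n0,design
Lam,12,12,24,26,cohort
Lombardi,15,16,29,35,cohort
McLeod,11,12,19,25,cohort
"Warren, 2002",1,2,6,8,cohort
"Warren, 2004",3,3,17,23,cohort
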