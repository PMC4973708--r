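study_id,r11,n1,r00,n0,design
Lo,11,11,56,89,cohort
Lombardi,13,16,31,35,cohort
McLeod,9,13,33,43,cohort
"Warren, 2002",3,4,10,12,cohort
"Warren, 2004",2,3,20,23,cohort
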