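study_id,r11,n1,r00,n0,design
Brennan,150,203,155,167,cohort
Davis,9,18,46,48,cohort
Green,8,9,12,12,cohort
Greenes,53,109,193,195,cohort
Hoffman,30,42,56,58,cohort
Hooker,10,15,24,24,cohort
Lanham,53,103,74,75,cohort
Muma,48,87,136,136,cohort
Nypaver,282,425,445,453,cohort
Rhoads,7,27,38,38,cohort
Stewart,57,59,20,20,cohort
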