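case,sex,age_at_diagnosis_yrs,stage,alk_inhibitor,alive,os_yrs,n_prois,avg_til_pct,avg_mucin_score,avg_stroma_score,n_trois,avg_immune_score
Case1,male,53.6,NA,Crizotinib,no,2.2,2,25.00,3.00,3.00,12,2.25
Case2,male,43.7,NA,Crizotinib,yes,6.6,2,25.00,2.00,2.00,12,2.00
Case3,male,68.9,NA,Crizotinib,no,4.1,6,15.00,2.00,1.67,12,2.00
Case4,female,32.8,3,Crizotinib,yes,13.8,3,23.33,3.00,2.33,12,1.42
Case5,female,68.5,NA,Crizotinib,yes,7.3,4,8.75,0.00,1.75,12,2.25
Case6,female,64.2,4,Alectinib,yes,4.9,3,28.33,0.00,1.00,12,1.60
Case7,male,66.7,3,Alectinib,yes,6.7,3,30.00,0.50,3.00,12,1.17
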