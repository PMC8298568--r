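patient_id,sex,age_at_operation_yr,implant_diameter_mm,event,months_post_fontan,min_diameter_mm,diameter_stenosis_pct,area_stenosis_pct,bsa_m2,elastic_modulus_kpa
P1,F,3,18,MRI I,6,18,0,0,0.64,13.14
P1,F,3,18,MRI II,36,9.4,48,61,0.74,10.51
P1,F,3,18,MRI III,60,8.8,51,63,NA,NA
P2,M,2,16,MRI I,6,6.8,58,72,0.53,16.00
P2,M,2,16,Catheter lab,7,5.6,65,84,NA,NA
P2,M,2,16,MRI II,36,7.9,51,72,0.67,8.00
P2,M,2,16,MRI III,60,11.5,28,36,NA,NA
P3,F,3,16,Catheter lab,5,6.5,59,82,NA,NA
P3,F,3,16,MRI I,6,7.1,56,79,0.53,16.00
P3,F,3,16,MRI II,36,7.5,53,68,0.67,17.00
P3,F,3,16,MRI III,60,10.5,34,71,NA,NA
P4,F,4,16,Catheter lab,5,3.6,78,94,NA,NA
P4,F,4,16,MRI I,6,6.8,58,79,0.68,14.72
P4,F,4,16,Catheter lab,7,6.6,59,80,NA,NA
P4,F,4,16,MRI II,36,8.6,46,65,0.83,13.67
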