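characteristic,level,n
sex,male,44
sex,female,42
location,right_sided_colon,30
location,left_sided_colon,20
location,rectum,36
stage,IIIA,10
stage,IIIB,61
stage,IIIC,15
tumor_classification,T1-2,12
tumor_classification,T3,64
tumor_classification,T4,10
nodal_status,N1,62
nodal_status,N2,24
histology,papillary_tubular,73
histology,poorly_mucinous_signet,13
adjuvant_chemotherapy,oxaliplatin_5fu,41
adjuvant_chemotherapy,5fu,45
recurrence,no,61
recurrence,yes,25
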