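test_type,sex,age_low,age_high,low,high
ph,any,0,Inf,7.20,7.40
pao2,any,0,Inf,70,90
pco2,any,0,Inf,35,45
potassium,any,0,Inf,3.5,5.0
hemoglobin,male,0,Inf,140,175
hemoglobin,female,0,Inf,123,153
sodium,any,0,90,136,145
sodium,any,90,Inf,132,146
hematocrit,male,0,Inf,0.42,0.50
hematocrit,female,0,Inf,0.36,0.45
wbc,any,0,Inf,4.5,11.0
co2_total,any,0,61,23,29
co2_total,any,61,91,23,31
co2_total,any,91,Inf,20,29
creatinine,male,0,60,80,115
creatinine,male,60,Inf,71,115
creatinine,female,0,60,53,97
creatinine,female,60,Inf,53,106
urea,male,0,56,3.0,9.0
urea,male,56,Inf,3.0,8.0
urea,female,0,56,3.0,8.0
urea,female,56,Inf,2.0,7.0
glucose,any,0,Inf,3.3,11.0
alt,male,0,Inf,0,60
alt,female,0,Inf,0,40
bilirubin,any,0,Inf,1.71,20.5
alp,any,0,Inf,40,120
albumin,any,0,Inf,30.0,45.0
ast,male,0,Inf,10,40
ast,female,0,Inf,9,32
ggt,male,0,Inf,0,80
ggt,female,0,Inf,0,50
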