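drug_code,drug_name,drug_class,default_units_per_day,min_antidepressant_dose_mg,ddd_mg
MPH10,methylphenidate 10 mg tablet,MPH,1,,30
CONC18,methylphenidate XR 18 mg tablet,MPH,1,,30
ATX25,atomoxetine 25 mg capsule,ATX,1,,80
FLU05,flumazenil 0.5 mg injection,FLUMAZENIL,1,,
FLX20,fluoxetine 20 mg capsule,AD_SSRI,1,20,20
SER50,sertraline 50 mg tablet,AD_SSRI,1,50,50
CIT20,citalopram 20 mg tablet,AD_SSRI,1,20,20
AMI25,amitriptyline 25 mg tablet,AD_TCA,1,75,75
IMI25,imipramine 25 mg tablet,AD_TCA,1,75,100
VEN75,venlafaxine 75 mg capsule,AD_OTHER,1,75,100
BUP150,bupropion 150 mg tablet,AD_OTHER,1,150,300
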