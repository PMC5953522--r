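id,display_name,group,urban_billable,rural_billable,order
hygiene_sanitation,Hygiene and environmental sanitation education/services,hygiene_environment,TRUE,TRUE,1
contraceptives,Provide contraceptives,family_health,TRUE,TRUE,2
anc_pnc,Provide antenatal and postnatal care,family_health,TRUE,TRUE,3
child_care,Provide care for sick and healthy children (including newborn),family_health,TRUE,TRUE,4
vaccination,Provide vaccinations,family_health,TRUE,TRUE,5
nutrition,Provide nutrition education/services,family_health,TRUE,TRUE,6
health_education,Provide other health education,family_health,TRUE,TRUE,7
hiv_education,Provide education/services on HIV/AIDS,disease_prevention,TRUE,TRUE,8
vct_hiv,Provide voluntary counseling and testing on HIV,disease_prevention,FALSE,TRUE,9
malaria,"Test, educate and provide malaria treatment",disease_prevention,TRUE,TRUE,10
first_aid,First-aid education and referral,first_aid,TRUE,TRUE,11
tb_services,Provide TB related services,disease_prevention,FALSE,TRUE,12
ncd,Screening and education for non-communicable diseases,ncd,TRUE,TRUE,13
group_training,Group training (Women's Development Army),group_training,TRUE,TRUE,14
travel,Travel,non_billable,FALSE,FALSE,15
recordkeeping,Recordkeeping and recording,non_billable,FALSE,FALSE,16
training_received,Receiving training and supervision,non_billable,FALSE,FALSE,17
idle,Idle or waiting time,non_billable,FALSE,FALSE,18
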