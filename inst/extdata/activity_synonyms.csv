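raw_label,category_id
Hygiene and Environmental Sanitation,hygiene_sanitation
hygiene and sanitation education,hygiene_sanitation
environmental sanitation services,hygiene_sanitation
Provide contraceptives,contraceptives
family planning counseling,contraceptives
contraceptive provision,contraceptives
Provide antenatal and postnatal care,anc_pnc
antenatal care,anc_pnc
postnatal care,anc_pnc
ANC visit,anc_pnc
PNC visit,anc_pnc
Provide care for sick and healthy children (includes newborn),child_care
sick child care,child_care
newborn care,child_care
well child visit,child_care
Vaccinations (Includes TT and Child),vaccination
vaccination session,vaccination
immunization,vaccination
TT vaccination,vaccination
child vaccination,vaccination
Provide nutrition education/services,nutrition
nutrition counseling,nutrition
growth monitoring,nutrition
Provide health education (education not covered elsewhere),health_education
health education session,health_education
general health education,health_education
Provide education/services on HIV/AIDS,hiv_education
HIV/AIDS education,hiv_education
HIV prevention education,hiv_education
Provide voluntary counseling & testing on HIV,vct_hiv
voluntary counseling and testing,vct_hiv
VCT,vct_hiv
HIV testing and counseling,vct_hiv
"Test, educate and provide malaria treatment",malaria
malaria testing,malaria
malaria treatment,malaria
RDT and malaria education,malaria
Provide first-aid (includes education and referral),first_aid
first aid,first_aid
first-aid and referral,first_aid
Non-communicable Diseases,ncd
NCD screening,ncd
blood pressure screening,ncd
Provide TB related services,tb_services
TB services,tb_services
TB treatment support,tb_services
Extended trainings (Women's Development Army),group_training
Women's Development Army training,group_training
WDA group training,group_training
community group training,group_training
travel,travel
travel to households,travel
walking between kebeles,travel
recordkeeping,recordkeeping
record keeping,recordkeeping
recordkeeping and recording,recordkeeping
updating family folders,recordkeeping
report writing,recordkeeping
receiving training and supervision,training_received
supervision received,training_received
in-service training,training_received
attending training,training_received
idle,idle
waiting,idle
break,idle
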