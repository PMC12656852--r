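alias,canonical
study,study_id
studyid,study_id
trial,study_id
reference,study_id
treatment,treatment_id
trt,treatment_id
diet,treatment_id
body_weight,bw
bodyweight,bw
weight,bw
ndf_gkg,ndf
ndf_g_kg,ndf
ether_extract,ee
fat,ee
crude_fat,ee
dm_intake,dmi
dry_matter_intake,dmi
om_intake,omi
organic_matter_intake,omi
ge_intake,gei
gross_energy_intake,gei
me_intake,mei
metabolizable_energy_intake,mei
ndf_intake,ndfi
adf_intake,adfi
om_digestibility,omd
omd_pct,omd
ndf_digestibility,ndfd
forage_pct,forage
forage_proportion,forage
fp,forage
ch4,ch4_g
ch4_gd,ch4_g
ch4_g_d,ch4_g
methane,ch4_g
methane_g_d,ch4_g
ch4_mjd,ch4_mj
ch4_mj_d,ch4_mj
methane_mj_d,ch4_mj
ch4_l,ch4_l
ch4_ld,ch4_l
ch4_l_d,ch4_l
methane_l_d,ch4_l
measurement_method,method
technique,method
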