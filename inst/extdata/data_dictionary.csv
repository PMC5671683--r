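"field","type","levels"
"record_id","id",""
"cluster_id","id",""
"maternal_age","integer",""
"ethnicity","category","white;mixed;other"
"literacy","category","none_or_primary;secondary_or_university"
"marital_status","category","married_or_stable;single_or_other"
"parity","category","nullipara;multipara"
"prenatal_visits","integer",""
"risk_exposure","flag","present;absent"
"previous_csection","flag","present;absent"
"labour_onset","category","spontaneous;induced;elective_csection"
"delivery_mode","category","csection;vaginal"
"death_status","category","alive;died_at_facility;died_in_transport_or_referral"
"hospital_stay_days","integer",""
"blood_transfusion","flag","present;absent"
"haemorrhage_any","flag","present;absent"
"eclampsia_or_mgso4","flag","present;absent"
"cardiac_disease","flag","present;absent"
"renal_disease","flag","present;absent"
"abruptio_placentae","flag","present;absent"
"ectopic_pregnancy","flag","present;absent"
"uterine_rupture","flag","present;absent"
"postpartum_haemorrhage","flag","present;absent"
"puerperal_sepsis","flag","present;absent"
"puerperal_infection","flag","present;absent"
"severe_preeclampsia_no_mgso4","flag","present;absent"
"severe_hypertension","flag","present;absent"
"placenta_previa_with_haemorrhage","flag","present;absent"
"other_severe_condition","flag","present;absent"
"anaemia","flag","present;absent"
"hiv_positive","flag","present;absent"
"diabetes","flag","present;absent"
"antenatal_admission","flag","present;absent"
"ovular_infection","flag","present;absent"
"urinary_tract_infection","flag","present;absent"
"other_maternal_condition","flag","present;absent"
"retained_placenta","flag","present;absent"
"referred","flag","present;absent"
"prev_diabetes","flag","present;absent"
"prev_hypertension","flag","present;absent"
"prev_preeclampsia","flag","present;absent"
"prev_eclampsia","flag","present;absent"
"prev_cardiac_disease","flag","present;absent"
"prev_renal_disease","flag","present;absent"
"prev_other_severe","flag","present;absent"
"prev_any","flag","present;absent"
"gestational_age_weeks","numeric",""
"birthweight_g","numeric",""
"apgar5","integer",""
"vital_status_at_birth","category","live;fetal_death"
"child_discharge_status","category","alive;neonatal_death;referred"
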