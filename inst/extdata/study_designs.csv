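# Study designs of the published clinical captopril studies used for model
# evaluation (doses, routes, demographics). One row per concentration-time
# profile (19 in all: 4 iv healthy, 11 oral healthy, 3 CKD, 1 CHF). Where
# the compiled source left a demographic blank ("-"), defaults are used:
# weight 55-85 kg, fraction_female 0. The 25 mg healthy study (n = 24,
# fraction_female 0.167, age 19-25, weight 45-86) contributes the test and
# reference profiles of a two-way bioequivalence design; column alignment
# of the compiled source was resolved against the cited reference.
profile_id,study_id,population,route,dose_mg,n_subjects,fraction_female,age_min,age_max,weight_min,weight_max,food_state
iv_2.78,2,healthy,iv_bolus,2.78,7,0,20,33,55,85,fasted
iv_5.67,2,healthy,iv_bolus,5.67,7,0,20,33,55,85,fasted
iv_10,1,healthy,iv_bolus,10,5,0,24,34,68.1,88.7,fasted
iv_11.4,2,healthy,iv_bolus,11.4,7,0,20,33,55,85,fasted
po_10,4,healthy,oral,10,5,0,24,34,68.1,88.7,fasted
po_25,5,healthy,oral,25,12,0,20,24,55,85,fasted
po_25_test,3,healthy,oral,25,24,0.167,19,25,45,86,fasted
po_25_ref,3,healthy,oral,25,24,0.167,19,25,45,86,fasted
po_50,5,healthy,oral,50,12,0,20,24,55,85,fasted
po_100_fasted,8,healthy,oral,100,12,0,18,33,60,106,fasted
po_100_fed,8,healthy,oral,100,12,0,18,33,60,106,fed
po_100_male,6,healthy,oral,100,12,0,21.88,25.78,67.53,76.85,fasted
po_100_female,6,healthy,oral,100,12,1,19.55,25.61,51.47,60,fasted
po_100,7,healthy,oral,100,10,0,18,35,64.2,85,fasted
po_100_geriatric,9,geriatric,oral,100,12,0,65,76,63,89,fasted
ckd_mild_100,10,ckd_mild,oral,100,4,0.75,19,60,57,109.5,fasted
ckd_moderate_100,10,ckd_moderate,oral,100,6,0.33,21,55,54.3,95.6,fasted
ckd_severe_100,10,ckd_severe,oral,100,8,0.62,19,62,47.4,90,fasted
chf_25,11,chf,oral,25,20,0,47,71,55,85,fasted
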