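# Observed and reference-predicted captopril PK parameters, transcribed
# from published clinical captopril studies as compiled (observed columns)
# and predicted (reference Simcyp PBPK analysis) in the published
# evaluation tables. Units: auc_0_inf ng/mL.h; cl L/h (CL/F for oral
# routes); cmax ng/mL. ratio_printed is the observed/predicted ratio as
# printed in the source tables (2 dp).
group,population,route,profile_id,dose_mg,parameter,observed,predicted,ratio_printed
iv_healthy,healthy,iv_bolus,iv_2.78,2.78,auc_0_inf,67.48,66.81,1.01
iv_healthy,healthy,iv_bolus,iv_5.67,5.67,auc_0_inf,123.21,134.70,0.91
iv_healthy,healthy,iv_bolus,iv_10,10,auc_0_inf,178.99,218.48,0.82
iv_healthy,healthy,iv_bolus,iv_11.4,11.4,auc_0_inf,310.82,279.21,1.11
iv_healthy,healthy,iv_bolus,iv_2.78,2.78,cl,41.20,41.61,0.99
iv_healthy,healthy,iv_bolus,iv_5.67,5.67,cl,46.01,42.09,1.09
iv_healthy,healthy,iv_bolus,iv_10,10,cl,55.86,45.77,1.22
iv_healthy,healthy,iv_bolus,iv_11.4,11.4,cl,36.67,40.83,0.90
iv_healthy,healthy,iv_bolus,iv_2.78,2.78,cmax,105.61,101.34,1.04
iv_healthy,healthy,iv_bolus,iv_5.67,5.67,cmax,120.52,206.91,0.58
iv_healthy,healthy,iv_bolus,iv_10,10,cmax,461.41,446.00,1.03
iv_healthy,healthy,iv_bolus,iv_11.4,11.4,cmax,458.73,471.04,0.97
oral_healthy,healthy,oral,po_10,10,auc_0_inf,100.51,115.68,0.87
oral_healthy,healthy,oral,po_25,25,auc_0_inf,335.59,304.54,1.10
oral_healthy,healthy,oral,po_25_test,25,auc_0_inf,348.67,318.55,1.09
oral_healthy,healthy,oral,po_25_ref,25,auc_0_inf,334.03,317.78,1.05
oral_healthy,healthy,oral,po_50,50,auc_0_inf,625.14,603.02,1.04
oral_healthy,healthy,oral,po_100_fasted,100,auc_0_inf,1339.39,1233.91,1.09
oral_healthy,healthy,oral,po_100_fed,100,auc_0_inf,782.07,1232.38,0.63
oral_healthy,healthy,oral,po_100_male,100,auc_0_inf,789.28,1121.55,0.70
oral_healthy,healthy,oral,po_100_female,100,auc_0_inf,781.54,1094.16,0.71
oral_healthy,healthy,oral,po_100,100,auc_0_inf,1198.67,1191.55,1.01
oral_healthy,geriatric,oral,po_100_geriatric,100,auc_0_inf,1415.87,1223.04,1.16
oral_healthy,healthy,oral,po_10,10,cl,99.48,86.45,1.15
oral_healthy,healthy,oral,po_25,25,cl,74.49,82.09,0.91
oral_healthy,healthy,oral,po_25_test,25,cl,71.70,78.48,0.91
oral_healthy,healthy,oral,po_25_ref,25,cl,74.84,78.67,0.95
oral_healthy,healthy,oral,po_50,50,cl,79.98,82.92,0.96
oral_healthy,healthy,oral,po_100_fasted,100,cl,74.66,81.04,0.92
oral_healthy,healthy,oral,po_100_fed,100,cl,127.86,81.14,1.58
oral_healthy,healthy,oral,po_100_male,100,cl,126.69,89.16,1.42
oral_healthy,healthy,oral,po_100_female,100,cl,127.95,91.39,1.40
oral_healthy,healthy,oral,po_100,100,cl,83.42,83.92,0.99
oral_healthy,geriatric,oral,po_100_geriatric,100,cl,70.62,81.76,0.86
oral_healthy,healthy,oral,po_10,10,cmax,66.48,72.96,0.91
oral_healthy,healthy,oral,po_25,25,cmax,138.09,192.29,0.72
oral_healthy,healthy,oral,po_25_test,25,cmax,215.01,192.29,1.12
oral_healthy,healthy,oral,po_25_ref,25,cmax,218.99,192.29,1.14
oral_healthy,healthy,oral,po_50,50,cmax,231.26,384.61,0.60
oral_healthy,healthy,oral,po_100_fasted,100,cmax,848.14,739.91,1.15
oral_healthy,healthy,oral,po_100_fed,100,cmax,338.75,792.63,0.43
oral_healthy,healthy,oral,po_100_male,100,cmax,480.65,750.21,0.64
oral_healthy,healthy,oral,po_100_female,100,cmax,466.16,817.07,0.57
oral_healthy,healthy,oral,po_100,100,cmax,768.17,747.28,1.03
oral_healthy,geriatric,oral,po_100_geriatric,100,cmax,735.90,676.34,1.09
disease,ckd_mild,oral,ckd_mild_100,100,auc_0_inf,1886.24,1715.13,1.10
disease,ckd_moderate,oral,ckd_moderate_100,100,auc_0_inf,2469.66,2321.50,1.06
disease,ckd_severe,oral,ckd_severe_100,100,auc_0_inf,6733.48,4612.70,1.46
disease,ckd_mild,oral,ckd_mild_100,100,cl,53.01,58.30,0.91
disease,ckd_moderate,oral,ckd_moderate_100,100,cl,40.49,43.08,0.94
disease,ckd_severe,oral,ckd_severe_100,100,cl,14.85,21.68,0.69
disease,ckd_mild,oral,ckd_mild_100,100,cmax,650,654.72,0.99
disease,ckd_moderate,oral,ckd_moderate_100,100,cmax,644,618.76,1.04
disease,ckd_severe,oral,ckd_severe_100,100,cmax,981,877.54,1.12
disease,chf,oral,chf_25,25,auc_0_inf,375.72,507.41,0.74
disease,chf,oral,chf_25,25,cl,66.54,49.27,1.35
disease,chf,oral,chf_25,25,cmax,240.21,240.56,1.00
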