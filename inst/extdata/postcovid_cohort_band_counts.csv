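score_id,domain,n_impaired,n_low_avg,n_avg_plus,n_total,pct_impaired,pct_low_avg,pct_avg_plus,pct_below_24
ravlt_trial_i,L+LTM,12,12,39,63,19.05,19.05,61.90,38.10
ravlt_trial_v,L+LTM,13,10,40,63,20.63,15.87,63.49,36.51
ravlt_total,L+LTM,16,17,30,63,25.40,26.98,47.62,52.38
ravlt_delayed_recall,L+LTM,17,8,38,63,26.98,12.70,60.32,39.68
ravlt_recognition,L+LTM,16,3,44,63,18.33,5.00,76.67,23.33
rocft_delayed_recall,L+LTM,13,18,32,63,20.63,28.57,50.79,49.21
objects_15,VVA,5,0,58,63,7.94,0.00,92.06,7.94
rocft_copy,VVA,6,15,42,63,9.52,23.81,66.67,33.33
rocft_time,VVA,5,7,51,63,7.94,11.11,80.95,19.05
block_design,VVA,3,9,51,63,4.76,14.29,80.95,19.05
forward_span,ST/WM,15,8,40,63,23.81,12.70,63.49,36.51
backward_span,ST/WM,6,7,50,63,9.52,11.11,79.37,20.63
coding,ProcessingSpeed,4,8,51,63,6.35,12.70,80.95,19.05
symbol_search,ProcessingSpeed,4,6,53,63,6.35,9.52,84.13,15.87
boston_naming,Language,5,4,54,63,7.94,6.35,85.71,14.29
phonemic_fluency,Language,11,11,41,63,17.46,17.46,65.08,34.92
semantic_fluency,Language,13,7,43,63,20.63,11.11,68.25,31.75
cpt_omissions,Attention,21,10,32,63,33.33,15.87,50.79,49.21
cpt_commissions,Attention,16,14,33,63,25.40,22.22,52.38,47.62
cpt_hit_rt,Attention,25,11,27,63,39.68,17.46,42.86,57.14
cpt_hit_se,Attention,33,16,14,63,52.38,25.40,22.22,77.78
cpt_variability,Attention,25,19,19,63,39.68,30.16,30.16,69.84
cpt_detectability,Attention,15,24,24,63,23.81,38.10,38.10,61.90
cpt_response_style,Attention,10,15,38,63,15.87,23.81,60.32,39.68
cpt_perseverations,Attention,20,1,42,63,31.75,1.59,66.67,33.33
cpt_hit_rt_block_change,Attention,11,17,35,63,17.46,26.98,55.56,44.44
cpt_hit_se_block_change,Attention,15,29,19,63,23.81,46.03,30.16,69.84
cpt_hit_rt_isi_change,Attention,18,21,24,63,28.57,33.33,38.10,61.90
cpt_hit_se_isi_change,Attention,15,18,30,63,23.81,28.57,47.62,52.38
tmt_a,EF,8,15,40,63,12.70,23.81,63.49,36.51
tmt_b,EF,12,17,32,61,19.67,27.87,52.46,47.54
stroop_color,EF,20,10,31,61,32.79,16.39,50.82,49.18
stroop_inhibition,EF,14,9,38,61,22.95,14.75,62.30,37.70
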