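"binary_id","louisville","tufts","kentucky","mother","cohort_n_louisville","cohort_n_tufts","cohort_n_kentucky","cohort_n_mother"
"high_pitched_crying",98,42,75,31,127,203,94,109
"sleeps_lt3h",70,108,80,82,127,203,94,109
"hyperactive_moro",36,35,64,42,127,203,94,109
"tremors_disturbed",119,163,64,85,127,203,94,109
"tremors_undisturbed",60,67,19,41,127,203,94,109
"increased_muscle_tone",120,182,87,99,127,203,94,109
"excoriation",36,48,20,21,127,203,94,109
"myoclonic_jerks",5,3,5,1,127,203,94,109
"generalized_convulsions",0,0,0,0,127,203,94,109
"sweating",8,10,8,6,127,203,94,109
"temp_ge_37_2",30,81,18,1,127,203,94,109
"yawning_gt3",4,14,3,4,127,203,94,109
"mottling",55,50,19,13,127,203,94,109
"nasal_stuffiness",25,21,13,13,127,203,94,109
"sneezing_gt3",40,67,41,34,127,203,94,109
"nasal_flaring",4,5,8,3,127,203,94,109
"resp_rate_gt60",57,60,41,53,127,203,94,109
"excessive_sucking",72,63,61,29,127,203,94,109
"poor_feeding",33,35,32,31,127,203,94,109
"regurgitation",25,24,27,19,127,203,94,109
"loose_watery_stools",32,34,38,28,127,203,94,109
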