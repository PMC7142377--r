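"item_id","grade","count"
"high_pitched_crying","excessive",187
"high_pitched_crying","continuous",28
"sleeps_after_feeding","less_than_3h",83
"sleeps_after_feeding","less_than_2h",96
"sleeps_after_feeding","less_than_1h",79
"moro_reflex","hyperactive",127
"moro_reflex","markedly_hyperactive",8
"tremors_disturbed","mild",201
"tremors_disturbed","moderate_severe",145
"tremors_undisturbed","mild",88
"tremors_undisturbed","moderate_severe",58
"muscle_tone","increased",389
"excoriation","present",104
"myoclonic_jerks","present",13
"convulsions","generalized",0
"sweating","present",26
"body_temperature","temp_37_2_to_38_3",129
"body_temperature","temp_ge_38_4",0
"yawning","more_than_3",21
"mottling","present",124
"nasal_stuffiness","present",59
"sneezing","more_than_3",148
"nasal_flaring","present",17
"respiratory_rate","over_60",138
"respiratory_rate","over_60_with_retractions",20
"excessive_sucking","present",196
"poor_feeding","present",100
"vomiting","regurgitation",76
"vomiting","projectile",0
"stools","loose",88
"stools","watery",16
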