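item,subscale,n_levels,reverse
q1,general_health,5,TRUE
q2,health_change,5,TRUE
q3,physical_functioning,3,FALSE
q4,physical_functioning,3,FALSE
q5,physical_functioning,3,FALSE
q6,physical_functioning,3,FALSE
q7,physical_functioning,3,FALSE
q8,physical_functioning,3,FALSE
q9,physical_functioning,3,FALSE
q10,physical_functioning,3,FALSE
q11,physical_functioning,3,FALSE
q12,physical_functioning,3,FALSE
q13,role_physical,2,FALSE
q14,role_physical,2,FALSE
q15,role_physical,2,FALSE
q16,role_physical,2,FALSE
q17,role_emotional,2,FALSE
q18,role_emotional,2,FALSE
q19,role_emotional,2,FALSE
q20,social_functioning,5,TRUE
q21,pain,6,TRUE
q22,pain,5,TRUE
q23,vitality,6,TRUE
q24,mental_health,6,FALSE
q25,mental_health,6,FALSE
q26,mental_health,6,TRUE
q27,vitality,6,TRUE
q28,mental_health,6,FALSE
q29,vitality,6,FALSE
q30,mental_health,6,TRUE
q31,vitality,6,FALSE
q32,social_functioning,5,FALSE
q33,general_health,5,FALSE
q34,general_health,5,TRUE
q35,general_health,5,FALSE
q36,general_health,5,TRUE
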