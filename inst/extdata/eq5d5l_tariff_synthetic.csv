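dimension,level,decrement
full_health,NA,1.0
mobility,2,0.05
mobility,3,0.10
mobility,4,0.20
mobility,5,0.30
self_care,2,0.04
self_care,3,0.08
self_care,4,0.16
self_care,5,0.25
usual_activities,2,0.03
usual_activities,3,0.07
usual_activities,4,0.14
usual_activities,5,0.22
pain_discomfort,2,0.06
pain_discomfort,3,0.12
pain_discomfort,4,0.24
pain_discomfort,5,0.35
anxiety_depression,2,0.05
anxiety_depression,3,0.11
anxiety_depression,4,0.22
anxiety_depression,5,0.33
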