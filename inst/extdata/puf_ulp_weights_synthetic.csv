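item,level,weight
wearing_comfort,1,0.0
wearing_comfort,2,-0.5
wearing_comfort,3,-1.0
wearing_comfort,4,-1.4
functionality,1,0.1
functionality,2,-0.4
functionality,3,-0.9
functionality,4,-1.4
independence,1,0.0
independence,2,-0.5
independence,3,-1.0
independence,4,-1.4
work_hobby_household,1,0.0
work_hobby_household,2,-0.5
work_hobby_household,3,-1.0
work_hobby_household,4,-1.4
user_friendliness,1,0.0
user_friendliness,2,-0.55
user_friendliness,3,-1.1
life_like_appearance,1,0.0
life_like_appearance,2,-0.5
life_like_appearance,3,-1.0
life_like_appearance,4,-1.4
phantom_limb_pain,1,0.0
phantom_limb_pain,2,-0.5
phantom_limb_pain,3,-1.0
phantom_limb_pain,4,-1.4
overuse_complaints,1,0.0
overuse_complaints,2,-0.5
overuse_complaints,3,-1.0
overuse_complaints,4,-1.4
reliability,1,0.0
reliability,2,-0.55
reliability,3,-1.1
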