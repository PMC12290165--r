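subject_id,loc_vigilance,loc_questions,motor_arm_left,motor_arm_right,best_language,dysarthria
P001,0,1,3,0,0,1
P002,0,0,0,4,1,2
P003,0,0,0,0,3,1
P004,1,2,1,1,2,0
P005,0,0,0,0,0,0
P006,0,1,2,0,0,1
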