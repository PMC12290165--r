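loc_item: loc_vigilance
item_max:
  loc_vigilance: 3
  loc_questions: 2
  motor_arm_left: 4
  motor_arm_right: 4
  best_language: 3
  dysarthria: 2
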