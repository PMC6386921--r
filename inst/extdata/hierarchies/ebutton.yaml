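# 15 activities of daily living over the four posture motion states of a
# chest-worn life logger. Multi-state activities (e.g. TU, RD, TK) appear in
# every group in which they can occur.
activities: [CU, ET, EM, MT, NP, RD, SP, SW, TK, TU, TP, WO, WU, TV, WT]
motion_states: [LY, SD, ST, WK]
correspondence:
  LY: [NP, TU]
  SD: [CU, ET, EM, MT, RD, SP, TK, TU, TP, TV, WT]
  ST: [ET, EM, RD, SP, SW, TK, TU, TP, WU]
  WK: [SP, WO]
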