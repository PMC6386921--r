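# 20 lifelogging activities grouped into 5 merged motion states.
activities: [WK, WK-US, WK-DS, RD-VU, RD-VD, RD-SU, RD-SD, SI, ET, DR,
             TX, MP, PC, RD, WT, OF, RN, DPU, DSU, CY]
motion_states: [WK/WK-US/WK-DS, SD/ST/CY, RN, DPU, DSU]
correspondence:
  WK/WK-US/WK-DS: [WK, WK-US, WK-DS]
  SD/ST/CY: [RD-VU, RD-VD, RD-SU, RD-SD, SI, ET, DR, TX, MP, PC, RD, WT, OF, CY]
  RN: [RN]
  DPU: [DPU]
  DSU: [DSU]
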