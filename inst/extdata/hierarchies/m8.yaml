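# 20 lifelogging activities grouped into 8 motion states; sedentary and
# standing are separate, so several activities belong to both groups and the
# correspondence is genuinely many-to-many.
activities: [WK, WK-US, WK-DS, RD-VU, RD-VD, RD-SU, RD-SD, SI, ET, DR,
             TX, MP, PC, RD, WT, OF, RN, DPU, DSU, CY]
motion_states: [WK/WK-US, WK-DS, SD, ST, RN, DPU, DSU, CY]
correspondence:
  WK/WK-US: [WK, WK-US]
  WK-DS: [WK-DS]
  SD: [SI, ET, DR, TX, MP, PC, RD, WT, OF]
  ST: [RD-VU, RD-VD, RD-SU, RD-SD, ET, DR, TX, MP, RD, OF]
  RN: [RN]
  DPU: [DPU]
  DSU: [DSU]
  CY: [CY]
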