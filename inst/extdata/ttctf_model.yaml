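# Two-factor measurement model for the synthetic five-subscore dataset
# (fluency F, originality O, abstractness of titles T, elaboration E,
# resistance to premature closure R -- columns y1..y5).
variables: [y1, y2, y3, y4, y5]
factors:
  innovation: [y1, y2]
  adaptation: [y3, y4, y5]
moderator: west
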