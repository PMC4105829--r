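# Example group definitions for a COPD-style case/control analysis.
# Predicates are R expressions over columns of the input table; rules are
# applied first-match-wins and unmatched subjects (e.g. GOLD 1, or subjects
# meeting neither definition) are dropped.
groups:
  case: "FEV1pp < 80 & fev1_fvc < 0.7"
  control: "FEV1pp >= 80 & fev1_fvc >= 0.7"
drop_unmatched: true
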