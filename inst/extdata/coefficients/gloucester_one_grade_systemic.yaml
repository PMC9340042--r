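# SYNTHETIC, illustrative coefficient set in the structure of the
# Gloucester variant using a single (index) retinopathy grading plus
# HbA1c, total cholesterol and diabetes duration.
model_id: gloucester-one-grade-demo
combine_mode: PH_POWER
categorical:
  variable: index_category
  levels:
    NO_DR: 0.0
    MILD_ONE_EYE: 1.4
    MILD_BOTH_EYES: 2.0
terms:
  - variable: hba1c_pct
    center: 6.8
    beta: 0.35
  - variable: total_cholesterol
    center: 5.0
    beta: 0.15
  - variable: duration_years
    center: 0
    beta: 0.03
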