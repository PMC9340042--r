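# SYNTHETIC, illustrative coefficient set in the structure of the
# Gloucester variant using two retinopathy gradings plus systemic
# covariates (HbA1c, total cholesterol) and diabetes duration.
model_id: gloucester-grades-systemic-demo
combine_mode: PH_POWER
categorical:
  variable: risk_group
  levels:
    A: 0.0
    D: 2.0
    E: 1.3
    F: 0.9
    G: 1.6
    H: 1.1
    I: 2.1
terms:
  - variable: hba1c_pct
    center: 6.8
    beta: 0.30
  - variable: total_cholesterol
    center: 5.0
    beta: 0.15
  - variable: duration_years
    center: 0
    beta: 0.02
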