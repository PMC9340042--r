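# SYNTHETIC, illustrative coefficient set in the structure of the Icelandic
# survival model (retinopathy-free survival on the time-since-diagnosis
# scale, proportional hazards over systemic covariates).  The published
# coefficient tables are NOT reproduced here; these values exist only to
# exercise the scoring engine.
model_id: icelandic-demo
combine_mode: PH_POWER
baseline:
  family: weibull
  shape: 1.25        # mildly increasing hazard with diabetes duration
  scale: 32.0        # years since diagnosis at which S0 = exp(-1)
terms:
  - variable: hba1c_pct
    transform: identity
    center: 6.8      # cohort mean HbA1c (%), so lp = 0 at reference values
    beta: 0.35
  - variable: sbp
    transform: identity
    center: 136      # cohort mean systolic BP (mm Hg)
    beta: 0.018
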