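# SYNTHETIC, illustrative coefficient set in the structure of the
# screening-only Gloucester model: one coefficient per two-screening risk
# group (A, D-I).  Groups B and C carry no coefficient by design — the
# model cannot score them.  Values are made up for demonstration.
model_id: gloucester-grades-demo
combine_mode: PH_POWER
categorical:
  variable: risk_group
  levels:
    A: 0.0
    D: 2.3
    E: 1.5
    F: 1.0
    G: 1.8
    H: 1.2
    I: 2.4
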