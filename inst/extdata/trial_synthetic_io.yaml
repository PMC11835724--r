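trial_id: SYNTH-IO-01
cancer_preset: aNSCLC-like
arms:
  treatment:
    regimens: combo_regimen
    line: 1
  control:
    regimens: control_regimen
    line: 1
biomarker:
  column: pdl1
  required_value: 1.0
  window_after_start: 30.0
strict:
  ecog_max: 2.0
  exclude_comorbidities:
  - comorb_chf
  - comorb_renal
  comorbidity_lookback_days: 365.0
  lab_limits:
    hemoglobin:
      min: 9.0
    creatinine:
      max: 2.0
    bilirubin:
      max: 3.0
  lab_lookback_days: 90.0
  exclude_met_sites: cns
  met_lookback_days: 90.0
standard_dose:
  min_first_dose: 150.0
benchmark:
  hr: 0.7
  ci_lower: 0.58
  ci_upper: 0.85
  endpoint: OS
  mos_treatment: 17.5
  mos_control: 12.5
crossover_allowed: no
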