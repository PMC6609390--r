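schema_version: 1
critical:
  PT:
    low: 9.0
    high: 70.0
    low_inclusive: yes
    high_inclusive: yes
  APTT:
    low: 15.0
    high: 100.0
    low_inclusive: yes
    high_inclusive: yes
  TT:
    low: ~
    high: 150.0
    low_inclusive: ~
    high_inclusive: no
  FBG:
    low: 1.0
    high: ~
    low_inclusive: no
    high_inclusive: ~
limited:
  PT:
  - 11.0
  - 16.3
  APTT:
  - 30.4
  - 46.4
  TT:
  - 14.0
  - 21.0
  FBG:
  - 2.0
  - 6.51
delta:
  PT:
    max_abs_delta: 10.0
    max_interval_days: 10
  APTT:
    max_abs_delta: 10.0
    max_interval_days: 7
  FBG:
    max_abs_delta: 1.0
    max_interval_days: 3
anticoagulated_override:
  max_interval_days: 30
  inr_low: 2.0
  inr_high: 3.0
logical:
- id: L1
  expr: (PT >= 14.00 | APTT >= 43.00) & FBG <= 2.00
- id: L2
  expr: PT >= 14.00 & APTT >= 43.00
- id: L3
  expr: APTT <= 43.00 & PT <= 14.00 & TT >= 21.00
contexts:
  warfarin:
    replace:
      PT:
        upper: 40.0
    inr_allowable:
      non_hip_surgery:
      - 1.5
      - 2.5
      hip_surgery:
      - 2.0
      - 3.0
      deep_vein_thrombosis:
      - 2.0
      - 3.0
      pulmonary_infarction:
      - 2.0
      - 4.0
      arterial_thrombosis_prevention:
      - 3.0
      - 4.0
      valve_prosthesis:
      - 3.0
      - 4.0
  heparin:
    replace:
      APTT:
        upper: 90.0
  thrombolytic:
    replace:
      FBG:
        lower: 1.2
        upper: 4.0
  late_pregnancy:
    scale:
      PT:
        upper: 0.9
      APTT:
        upper: 0.9
      FBG:
        lower: 1.1
qc_policy:
  max_qc_age_hours: 24.0
  rejection_rules:
  - 1_3s
  - 2_2s
  - R_4s
  - 4_1s
  - 10_x
reference_intervals:
  PT:
  - 11.0
  - 14.3
  APTT:
  - 32.0
  - 43.0
  TT:
  - 14.0
  - 21.0
  FBG:
  - 2.0
  - 4.0
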