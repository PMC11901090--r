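# Model inputs for the breast-reconstruction cost-effectiveness analysis.
# Costs are 2024 USD (Medicare reimbursement, payer perspective); utilities
# are trajectory-level expected B-QALYs over the 5-year base-case horizon.
# Transition blocks hold prior (uncalibrated) monthly rates reflecting the
# qualitative ordering complication risk implant > abdominal flap > O-FAFF
# and revision rate lowest for O-FAFF; run calibrate_model() to obtain the
# rates and recurring medication costs that reproduce the published
# incremental results. pain_medication_monthly is a recurring monthly cost
# with no published value; it defaults to 0 here and is assigned by
# calibration.
strategies:
  O-FAFF:
    costs:
      surgical_materials: 7974.48
      anesthesia: 828.29
      hospital_stay: 8649.00
      salvage: 350.87
      loss: 350.87
      revision: 1574.01
      pain_medication_monthly: 0
    utilities:
      no_complication: 3.74
      loss: 0.03
      salvage: 3.48
      revision: 3.49
    transitions:
      p_complication_monthly: 0.0015
      p_salvage_given_complication: 0.90
      p_revision_monthly: 0.005
      revision_window: [7, 24]
      anesthesia_mortality_multiplier: 1.5
    inpatient_days: 3
    age_mean: 49
    age_sd: 8
    bmi_mean: 22.1
    bmi_sd: 3
    nipple_sparing_pct: 78
    followup_months_mean: 22
    followup_months_sd: 8
  ABDOMINAL_FLAP:
    costs:
      surgical_materials: 2703.94
      anesthesia: 580.35
      hospital_stay: 8649.00
      salvage: 3205.04
      loss: 350.87
      revision: 1574.01
      pain_medication_monthly: 0
    utilities:
      no_complication: 3.55
      loss: 0.03
      salvage: 3.30
      revision: 3.31
    transitions:
      p_complication_monthly: 0.005
      p_salvage_given_complication: 0.90
      p_revision_monthly: 0.030
      revision_window: [7, 24]
      anesthesia_mortality_multiplier: 1.5
    inpatient_days: 3
    age_mean: 51
    age_sd: 9
    bmi_mean: 27.4
    bmi_sd: 5
    nipple_sparing_pct: 35
    followup_months_mean: 49
    followup_months_sd: 10
  IMPLANT:
    costs:
      surgical_materials: 4973.82
      anesthesia: 197.54
      hospital_stay: 0
      salvage: 2269.13
      loss: 269.13
      revision: 1574.01
      pain_medication_monthly: 0
    utilities:
      no_complication: 3.38
      loss: 0.08
      salvage: 3.14
      revision: 3.15
    transitions:
      p_complication_monthly: 0.009
      p_salvage_given_complication: 0.50
      p_revision_monthly: 0.020
      revision_window: [7, 24]
      anesthesia_mortality_multiplier: 1.5
    inpatient_days: 0
    age_mean: 55
    age_sd: 9
    bmi_mean: 26.1
    bmi_sd: 4
    nipple_sparing_pct: 59
    followup_months_mean: 72
    followup_months_sd: 12
settings:
  horizon_years: 5
  cycle_length_months: 1
  annual_discount_rate: 0.03
  n_patients: 10000
  wtp_thresholds: [50000, 100000, 200000]
  seed: 1
  cohort_age_mean: 52
  cohort_age_sd: 9
  cohort_sex: female
life_table:
  type: synthetic
  base_annual_mortality_at_50: 0.004
  doubling_time_years: 8
  anesthesia_multiplier: 1.5
  age_min: 18
  age_max: 100
  sex: female
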