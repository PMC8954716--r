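# Default stratification rules for the seven lifetime cardiovascular risk
# factors measured at 6 months postpartum. Each numeric factor maps a
# measurement to one of four strata (optimal, not_optimal, elevated, major)
# via ordered breaks: value < breaks[1] -> optimal, [breaks[1], breaks[2])
# -> not_optimal, [breaks[2], breaks[3]) -> elevated, >= breaks[3] -> major.
# Boolean factors map FALSE -> optimal and TRUE -> true_stratum.
#
# EXTERNAL PROVENANCE: these default thresholds are transcribed from the
# Framingham lifetime-risk stratification literature (risk-factor burden
# categories), with glucose cut-points aligned to standard impaired-fasting-
# glucose / diabetes definitions. They are a starting point, fully editable;
# the categorization machinery is the tested contract, not these numbers.
version: "1.0"
factors:
  total_cholesterol:
    type: numeric
    units: mmol/L
    breaks: [4.7, 5.2, 6.2]
    admissible: [1.0, 15.0]
  systolic_bp:
    type: numeric
    units: mmHg
    breaks: [120, 140, 160]
    admissible: [60, 260]
  diastolic_bp:
    type: numeric
    units: mmHg
    breaks: [80, 90, 100]
    admissible: [30, 160]
  fasting_glucose:
    type: numeric
    units: mmol/L
    breaks: [5.6, 6.1, 7.0]
    admissible: [2.0, 30.0]
  antihypertensive_use:
    type: boolean
    true_stratum: major
  diabetes_diagnosis:
    type: boolean
    true_stratum: major
  current_smoker:
    type: boolean
    true_stratum: major
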