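# Example pipeline configuration. Paths left unset fall back to the shipped
# fixtures; benefit-model constants may be overridden per measure.
measures: [crc_screening, bp_control]
scenarios: [p66, p90]
weight_rule: percentile_width
horizon_years: 10
seed: 1
benefit_models:
  bp_control:
    nnt_death: 101
    annualization: trial
    trial_followup_years: 4
    nnt_event: 80.72
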