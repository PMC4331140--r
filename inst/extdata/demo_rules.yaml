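# Illustrative alert criteria for the daily activity summary. The alert
# mechanism is generic; these rules only demonstrate the predicate forms
# (any-event, value threshold, count-in-window).
rules:
  - id: resp_admission_any
    concepts: [resp_admission]
  - id: low_fev1_pct
    concepts: [fev1_pct_pred]
    value_op: "<"
    value_threshold: 30
  - id: ocs_2_in_30d
    concepts: [ocs]
    min_count: 2
    window_days: 30
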