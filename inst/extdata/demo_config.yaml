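# Demonstration pipeline configuration: a small registry, two corrupted
# extraction routes, standard cohorts, one year of follow-up, and a month
# of daily alert batches. Runs end-to-end in well under two minutes.
seed: 20090101
out_dir: results
generator:
  n_adults: 3504
sources:
  sir:
    drop_patient_prob: 0.008
    drop_record_prob:
      prescription: 0.0001
      event: 0.009
  apollo:
    drop_patient_prob: 0.003
    drop_record_prob:
      prescription: 0.0002
      event: 0.0001
    duplicate_record_prob: 0.0005
followup_window: ["2009-01-01", "2010-01-01"]
alert_rules: demo_rules.yaml
alert_days: 28
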