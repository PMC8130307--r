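# Demonstration pipeline configuration: a synthetic hospital cohort and a
# synthetic spontaneous-report corpus with one planted ototoxicity signal
# (drug_pos) and one null drug (drug_null). Runs end to end in well under a
# minute.
seed: 42
candidate_drugs: [drug_pos, drug_null]
outcome_codes: [EAR_DISORDER]
adr_code: ear_disorder
window_days: 365
caliper_sd: 0.2
sim_ehr:
  n_patients: 20000
  baseline_event_hazard: 1.0e-4
  drugs:
    drug_pos: {prevalence: 0.08, log_hr: 0.6931}   # true hazard ratio 2
    drug_null: {prevalence: 0.08, log_hr: 0.0}
  exposure_coefs: {age: 0.03, visits: 0.02}        # confounded exposure
  outcome_coefs: {age: 0.02, visits: 0.01}
  pta:
    fraction: 0.05
    baseline_abnormal_prob: 0.05
    exposed_abnormal_prob: 0.05
    effect_drugs: []
sim_srs:
  n_reports: 50000
  drug_probs: {drug_pos: 0.02, drug_null: 0.02}
  reaction_probs: {ear_disorder: 0.01}
  planted:
    - {drug: drug_pos, reaction: ear_disorder, log_ror: 0.6931}  # ROR 2
case_def:
  systemic_disease_codes: []
  ear_surgery_codes: []
  ototoxic_drug_codes: []
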