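# End-to-end demo on a small simulated cohort: simulate -> AGE-Index ->
# pattern classification -> sex bias -> clock training -> prediction ->
# coefficient-sign enrichment. Run with:
#   run_pipeline(system.file("extdata", "demo_config.yaml", package = "diage"),
#                out_dir = tempfile("demo"))
seed: 42
simulate:
  n_samples: 80
  n_genes: 400
  p_young: 0.6
  n_inflammaging: 20
  inflammaging_fold: 8
  onset_day: 3
  n_male_biased: 4
  male_bias_mult: 8
  n_female_suppressed: 4
  female_young_mult: 0.2
  female_suppressed_fold: 4
  noise_sd: 0.2
age_index:
  young: [3, 10]
  old: 30
  pseudocount: 0.1
classify:
  inflammaging_threshold: 5
  low_partner_ceiling: 2
  skew_ratio: 3
sex_bias:
  age_window: [3, 10]
  pseudocount: 0.5
train:
  alpha: 0.5
  split: 0.7
  sex_filter: all
  k: 5
enrich:
  sets: planted
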