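# Default calibrated synthetic-cohort configuration.
# Baseline Weibull solved so that, at a null linear predictor, the latent
# debut age has median 16 years and P(debut < 15) = 0.189.
n_clusters: 250
persons_per_cluster: 20
baseline:
  a0: 8.0
  shape: 9.0
  scale: 8.3325139013
interview_age: [15.0, 25.0]
integer_year_rounding: true
seed: 11
weight_model:
  dist: uniform
  min: 0.2
  max: 1.0
covariates:
  sex:
    levels: [male, female]
    probs: [0.5, 0.5]
    beta: [0.0, 0.0]
  residence:
    levels: [urban, rural]
    probs: [0.45, 0.55]
    beta: [0.0, 0.0]
  alcohol:
    levels: [no, yes]
    probs: [0.8, 0.2]
    beta: [0.0, 0.4054651081]
  away_from_home:
    levels: [yes, no]
    probs: [0.22, 0.78]
    beta: [0.0, -0.1053605157]
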