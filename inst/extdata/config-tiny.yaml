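population:
  population_size: 2000
  strata:
  - professionals
  - technicians
  - administrative
  strata_proportions:
  - 0.505
  - 0.28
  - 0.215
  smoking_prevalence:
  - 0.159
  - 0.209
  - 0.253
  stratum_hr:
  - 1.0
  - 1.5
  - 3.0
  smoking_hr:
  - 1.5
  - 2.0
  - 3.0
  weibull_shape: 2.0
  weibull_scale: 99.2217
  censor_horizon: 40.0
scenarios:
- name: strat-full-weighted
  design:
    kind: stratified
    allocation:
      professionals: 120.0
      technicians: 180.0
      administrative: 300.0
  loss:
    mode: none
  model: full
  weighted: yes
  replicates: 20
- name: strat-marginal-weighted
  design:
    kind: stratified
    allocation:
      professionals: 120.0
      technicians: 180.0
      administrative: 300.0
  loss:
    mode: none
  model: marginal
  weighted: yes
  replicates: 20
- name: strat-marginal-unweighted
  design:
    kind: stratified
    allocation:
      professionals: 120.0
      technicians: 180.0
      administrative: 300.0
  loss:
    mode: none
  model: marginal
  weighted: no
  replicates: 20
seed: 101
output_dir: tiny-results
verbose: no
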