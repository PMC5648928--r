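master_seed: 4242
n_per_curve: 10000
parameters:
  volume:
  - stage: I
    mu: 1.72
    sigma: 4.7
    lower: 0.3
    upper: 5.0
  - stage: II
    mu: 1.96
    sigma: 1.63
    lower: 0.3
    upper: 13.0
  - stage: IIIA
    mu: 1.91
    sigma: 0.94
    lower: 0.3
    upper: 13.0
  - stage: IIIB
    mu: 2.76
    sigma: 0.687
    lower: 0.3
    upper: 13.0
  - stage: IV
    mu: 3.86
    sigma: 0.882
    lower: 0.3
    upper: 13.0
  rho_mu: 7.0e-05
  rho_sigma: 0.00723
  alpha_mu: 0.0398
  alpha_sigma: 0.168
  correlation: 0.87
  beta_c_mu: 0.028
  beta_c_sigma: 0.0007
  carrying_capacity_diameter: 30.0
  delay_min: 14.0
  delay_max: 21.0
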