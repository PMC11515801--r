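# Default 320-scenario study grid:
# 5 designs x 2 intervention effects x 4 between-cluster variances
# (ICC 0.01, 0.05, 0.1, 0.2) x 2 mean cell sizes x 4 scenario types.
designs: [3, 4, 5, 6, 10]
deltas: [0.0, 0.5]
tau2s: [0.01010101010101010, 0.05263157894736842, 0.1111111111111111, 0.25]
cell_sizes: [30, 100]
scenario_types: [none, chance_imbalance, covariate_confounding, complete_confounding]
period_slope: 0.2
sigma2_w: 1.0
theta: 1.0
xi_imbalance: 0.3
base_seed: 1
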