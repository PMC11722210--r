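# Default run configuration for the tssACE pipeline. Every key is
# optional; missing keys fall back to the package defaults (these
# values). CLI flags override keys in this file.
scenario:
  name: LARGE          # LARGE | MEDIUM | SMALL (generating candidate 3/2/1)
  n_cells: 8000        # total cells at time 0 (halved into observed/pool)
  t: 1.5               # evolution time, seconds
  mu: [5.25, 7.60, 5.25, 7.60, 5.25, 5.25]        # log-scale locations
  sigma2: [0.15, 0.06, 0.15, 0.06, 0.15, 0.15]    # log-scale variances
  # true_rates: [2.0e-4, 9.0e-3, 2.0e-3]  # default: per-scenario rates
network: null          # path to a network YAML; null = built-in model
gmm:
  moments: [means, variances, covariances]
  weights: invvar      # invvar | relative | unit
  n_starts: 8
  lower: 1.0e-8
  upper: 100.0
  search_size: 500      # pool subsample during multi-start search
density:
  bandwidth: silverman
  cdf_clip: 1.0e-6
selection:
  B: 200
  reestimate: false
output_dir: tssace_out
seed: 1
log_level: info
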