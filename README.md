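# tssACE

Entropy-based model selection for mass-action ODE models calibrated
against time-stamped snapshot (TSS) single-cell data.

## The problem

Single-cell assays measure protein abundances across thousands of cells
but destroy each cell they measure, so the population observed at time
*t* is unpaired with the population observed at time 0. For signaling
models written as mass-action ODEs with cell-to-cell variability entering
through random initial conditions (extrinsic noise), the likelihood of a
candidate model is unavailable: the model's predicted distribution at
time *t* exists only as the push-forward of the initial-condition
distribution through the ODE flow. Standard likelihood-based selection
(AIC and relatives) does not directly apply, yet practitioners routinely
face several mechanistic candidates for the same data.

## The method

For candidate model *i* with free rate parameters θ:

* **GMM estimation.** θ̃ᵢ minimizes a weighted sum of squared differences
  between the first and second moments (means, variances, covariances) of
  the observed time-*t* cells and the moments of a reserved pool of
  time-0 cells evolved to *t* under the candidate. Weights default to
  inverse delta-method sampling variances of the target moments.
* **Predictive density by Sklar's theorem.** From the evolved pool,
  ĥᵢ(y | θ̃ᵢ) = c(F̂₁(y₁), …, F̂ₙ(yₙ)) · ∏ₖ f̂ₖ(yₖ), with log-scale
  Gaussian-kernel marginals f̂ₖ (Silverman bandwidth) and a Gaussian
  copula c fitted on rank/(N+1) pseudo-observations.
* **Approximate cross-entropy.** ACEᵢ = (1/𝒩) Σⱼ −log ĥᵢ(yⱼ | θ̃ᵢ) over
  held-out observed cells. Since CE(f‖h) = H(f) + KL(f‖h) and H(f) is
  candidate-independent, the minimum-ACE candidate is the minimum-KL
  candidate. A 20/80 split of the observed cells separates estimation
  from selection.
* **Approximate AICc cross-check.** The vector of observed-minus-predicted
  mean abundances Δ is modelled as independent zero-mean normals with
  s²ⱼ = var(obs)ⱼ/N_y + var(pred)ⱼ/N_x, giving
  AICc = −2 log L(Δ) + 2k + 2k(k+1)/(n−k−1) with n = number of proteins
  and k = number of free parameters (defined only for k < n−1).
* **Bootstrap selection probabilities.** The fraction of bootstrap
  resamples of the evaluation cells in which each candidate attains the
  minimum ACE.

The built-in study is a six-species NK-cell signaling network (Syk, Vav1,
SykVav1, pVav1, SHP1, SHP1pVav1; three fixed rates 0.12, 0.14, 0.05) with
three nested candidates: CM1 (θ₂ = 9θ₁, θ₃ = 2θ₁), CM2 (θ₂ = 9θ₁) and
CM3 (all free). Scenarios SMALL/MEDIUM/LARGE generate 8,000-cell
populations from CM1/CM2/CM3 with lognormal initial conditions
(μ = (5.25, 7.60, 5.25, 7.60, 5.25, 5.25), σ² = (0.15, 0.06, 0.15, 0.06,
0.15, 0.15)) evolved to t = 1.5 s.

## Worked example

```r
library(tssACE)

cfg <- simulator_config(n_cells = 8000, scenario = "LARGE", seed = 1)
bundle <- generate_scenario(cfg)
bundle
report <- run_model_selection(bundle)
report
boot <- bootstrap_model_selection(bundle, B = 200, seed = 1, report = report)
boot
```

```
Scenario LARGE (generating candidate 3 )
  observed: 4000 cells at t = 1.5 s
  candidate pool: 4000 cells at t = 0
  split: 800 estimation / 3200 evaluation cells
  true rates: 2e-04, 0.2, 8e-04
Entropy-based model selection (scenario LARGE)
  candidate n_free     ACE     AICc converged
1       CM1      1 46.5073 5510.700      TRUE
2       CM2      2 34.6524   94.490      TRUE
3       CM3      3 34.4043   50.607      TRUE
Selected by ACE: CM3; by AICc: CM3
ACE gap (|best - runner-up|): 0.2481 nats; 3200 evaluation cells
Bootstrap model selection (B = 200, reestimate = none) scenario LARGE
ACE selection probabilities:
CM1 CM2 CM3
  0   0   1
AICc selection probabilities:
CM1 CM2 CM3
  0   0   1
ACE/AICc concordance: 1
P(correct model selected): 1
```

Reading the output: the generating model here is CM3, and both criteria
recover it. The per-candidate ACE values are mean negative log predictive
densities in nats over the 3,200 evaluation cells — lower is better, and
only differences between candidates are meaningful (the absolute level is
dominated by the entropy of the population itself). The one-parameter
candidate misfits badly (ACE 46.5 vs 34.4, AICc in the thousands); the
two-parameter candidate comes much closer but cannot reproduce the free
phosphorylation rate, and loses by 0.25 nats of ACE and by ~44 AICc
units. The bootstrap probabilities are the fraction of 200
evaluation-cell resamples each candidate wins; with fixed parameter
estimates these concentrate sharply (see the vignette for why, and for
the `reestimate = "linearized"` mode that propagates estimation noise
instead).

## Command line

```sh
Rscript inst/scripts/tssace.R simulate  --config my_run.yaml --out out/
Rscript inst/scripts/tssace.R select    --config my_run.yaml
Rscript inst/scripts/tssace.R bootstrap --config my_run.yaml --B 200
```

`inst/extdata/default_run_config.yaml` documents every key; CLI flags
override config keys, which override package defaults. Exit codes:
0 success, 2 config error, 3 data error, 4 numerical failure.

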