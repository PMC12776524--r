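# regnn — regression-guided neural networks for effect-measure modification

Epidemiologists and social scientists routinely ask *who is most harmed* by
an exposure: does air pollution damage cognition more for some people than
for others? The standard tool, moderated multiple regression (MMR), adds
exposure-by-moderator product terms

> o = c₀ + Σₖ cₖxₖ + cₙx_f + Σₖ cₖⁱⁿᵗ xₖ x_f + e,

but collapses when vulnerability is spread across many correlated
covariates: the interaction block is multicollinear, power evaporates, and
higher-order moderation has to be guessed in advance.

`regnn` implements the **regression-guided neural network** (ReGNN): a
semi-parametric estimator that replaces the whole interaction block with a
single learned term,

> o = c₀ + Σₖ cₖxₖ + cₙx_f + c_int · f(X_p) · x_f + e,

where f is a small multi-layer perceptron trained **jointly** with the
regression coefficients by stochastic gradient descent on the (optionally
survey-weighted) MSE. The scalar z = f(X_p) is a composite moderator — a
*vulnerability index* — and the marginal effect of the exposure at index
level z′ is simply cₙ + c_int·z′. Freezing the network and refitting the
"twin" regression with z as an observed covariate restores everything a
regression user expects: coefficients, standard errors, t statistics,
p-values, confidence intervals, VIFs.

The package covers the whole workflow:

* `simulate_regnn_data()` — synthetic populations with correlated
  mixed-type covariates and a planted pair/triplet polynomial moderator,
  at chosen signal-to-noise ratios;
* `regnn()` — joint training (two learning-rate groups, dropout, Adam or
  momentum SGD, seeded and deterministic), with `predict()`, `tidy()`,
  `glance()`, `autoplot()` and `compute_index()`;
* `fit_twin()`, `fit_mmr()`, `marginal_effect()`, `predict_profiles()`,
  `sensitivity_probe()`, `vif()` — classical inference around the frozen
  index, including the small-held-out-set probe that flags overfit
  moderation;
* `recovery_correlation()`, `recall_at_quantile()`,
  `precision_recall_curve()`, `evaluate_recovery()` — recovery metrics
  against the planted truth;
* `shap_values()`, `shap_importance_cv()`, `rank_discrepancy()`,
  `fit_gmm()`, `match_clusters()`, `threshold_sweep()`,
  `partial_dependence()` — post-hoc interpretation: cross-validated
  Shapley importance and Gaussian-mixture clustering of the vulnerable
  subgroup with Mahalanobis cluster matching;
* `run_simulation_study()` / `report()` — the end-to-end replicate study.

## Worked example

```r
library(regnn)

sim <- simulate_regnn_data(n = 4000, snr = 5, seed = 1)  # planted moderator M
fit <- regnn(sim, snr = 5, seed = 1)                     # joint training
fit
#> <regnn> MLP (35, 60, 32, 1), 100 epochs, batch 50, optimizer adam
#>   exposure `xf`: cn = 0.3218, interaction cint = 0.4058 (orientation -1)
#>   final training loss 0.1265; splits: train 3200 / sensitivity 80 / holdout 720

tw <- fit_twin(fit, subset = "train")                    # frozen-index inference
dplyr::filter(tidy(tw), term %in% c("xf", "z", "xf:z"))
#> # A tibble: 3 × 8
#>   term  estimate std.error statistic   p.value conf.low conf.high   vif
#> 1 xf     0.294     0.00846    34.7   2.78e-224  0.277     0.310    3.23
#> 2 z      0.00191   0.00350     0.546 5.85e-  1 -0.00495   0.00876  1.27
#> 3 xf:z   0.416     0.00277   150.    0          0.410     0.421    1.06

sensitivity_probe(fit)                                   # honest 2% held-out probe
#> <sensitivity_probe> n = 80 (sensitivity set): interaction p-value = 4.7e-12

recovery_correlation(fit$z, sim$truth$M)                 # vs the planted truth
#> [1] 0.9130813
recall_at_quantile(fit$z, vulnerable_mask(sim$truth$M, 0.84)$mask)
#> [1] 0.7546875
```

Reading the numbers: the learned index moderates the exposure with
overwhelming significance (`xf:z`, t ≈ 150 on the training set, and
p ≈ 5·10⁻¹² even on the 80-row held-out probe), its VIF stays low (1.06 —
no multicollinearity penalty, unlike all-moderator MMR), the index
correlates 0.91 with the planted moderator, and thresholding both at their
84th percentile recovers ~75% of the truly vulnerable group. At low SNR
the probe p-value rises above 0.05, flagging that the learned moderation
is no longer trustworthy — that is the intended use of the sensitivity set.

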