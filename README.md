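# mvclmeta

Meta-analysis of **rare binary adverse events**: a one-stage multilevel
logistic estimator of the pooled odds ratio, the five classical two-stage
estimators, a trial simulator built around the *rule of three*, and a
Monte-Carlo harness that scores them all.

## Who this is for

Biostatisticians and evidence-synthesis methodologists who need to pool
sparse 2×2 tables — adverse-event meta-analyses where most trials observe
zero to a handful of events — and want either (a) the estimators themselves
on their own data, or (b) a simulation framework for studying estimator
bias, MSE, coverage and interval width when trials are sized by the
rule-of-k heuristics (`n = k/p` subjects per arm to have a good chance of
seeing at least `k` events of probability `p`).

## The model at the core

The one-stage estimator fits all arms of all studies jointly as a binomial
generalized linear mixed model (the multilevel variance-component logistic
model, MVCL):

    y_ij ~ Bin(n_ij, p_ij),   logit(p_ij) = α₀ + u_j + θ·x_ij,   u_j ~ N(0, σ_u²)

with `x = 1` for the treatment arm; the pooled odds ratio is `exp(θ)` and
latent-scale heterogeneity is `I² = σ_u²/(σ_u² + π²/3)`. Fitting is by
maximum marginal likelihood with adaptive Gauss–Hermite quadrature —
implemented from scratch in this package and cross-validated against
`lme4::glmer` in the test suite.

The two-stage comparators: inverse-variance weighted log odds ratios
(fixed, and DerSimonian–Laird random effects), classical Mantel–Haenszel
pooling (ratio of sums with the Robins–Breslow–Greenland variance), and the
Peto O−E/V estimator. Zero-cell studies get a 0.5 continuity correction on
the IV path; double-zero studies are excluded from two-stage pooling but
retained in the one-stage likelihood.

## Worked example

```r
library(mvclmeta)

# a rule-of-three scenario: pc = 0.01 so n = 300 per arm, true OR = 2
sc <- scenario(pc = 0.01, or_true = 2, tau = 0.1, m = 10, rule_k = 3,
               scenario_id = 17)
ms <- simulate_meta_sample(sc, replicate_id = 1, seed = 42)

fit_mvcl(ms)
#> One-stage MVCL fit
#>   OR = 1.7643 (95% CI 1.1393-2.7321)
#>   theta = 0.5677 (SE 0.2231), alpha0 = -4.5299
#>   sigma_u2 = 0.0000, I2 = 0.0% (latent scale), logLik = -455.540

pool_weighted(study_effects(ms), "iv", "random")
#> [iv_random] OR = 1.7344 (95% CI 0.9613-3.1292), log-OR SE = 0.3011, k = 10
#>   tau2 = 0.2808, I2 = 26.9%

pool_peto(ms)
#> [peto] OR = 1.7388 (95% CI 1.1415-2.6485), log-OR SE = 0.2147, k = 10
```

The three point estimates agree closely (this draw is not very sparse), but
the one-stage fit, which found no between-study variance it could attribute
to heterogeneity (`sigma_u2 = 0`), gives a noticeably tighter interval than
the DerSimonian-Laird analysis, whose moment estimator reacts to the
scatter of the study log odds ratios. The simulation grid is where the
estimators separate systematically:

```r
out <- run_scenario(grid_scenario(1), reps = 1000, seed = 1)
out$summary[, c("method", "pct_bias", "mse", "coverage", "avg_ci_width")]
```

At scenario 1 (pc = 0.05, 60/arm, OR = 1.25, tau = 0.1, m = 10) the
one-stage estimator's percentage bias is ≈ +3–5% while interval coverage
stays near 95%; under the rule of one (scenario 3) it degrades to ≈ +14%,
and under substantial heterogeneity (tau = 1, scenario 31) every method is
biased upward by 30–60%.

A command-line interface mirrors this: see
`inst/scripts/mvclmeta` (`simulate`, `fit`, `summarize` subcommands).

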