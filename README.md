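# stagegrow

Hierarchical Bayesian growth modelling for stage-structured animal
populations whose life stages are monitored with incompatible sampling
designs. The motivating case is a pond-breeding salamander: aquatic larvae
are dip-netted and can be aged from the date their wetland filled (age 0),
metamorphs are caught emigrating at an unknown age, and long-lived
terrestrial adults are PIT-tagged at drift fences and remeasured across
years without ever knowing their age. `stagegrow` reconciles all three
data streams into one joint model of growth from hatching to old age.

## The model

Lengths follow von Bertalanffy growth curves with a shift at
metamorphosis. For a larva of known age *t*:

    L_t = L∞ (1 − e^(−k_L (t − t₀)))

A metamorph's length is the same curve evaluated at its latent age at
metamorphosis *t_m* ~ U(0.2, 0.7) years. An adult first captured at latent
age *t* (truncated lognormal, log-median log α, log-variance σ_t²) and
remeasured δt years later follows

    L_t = L∞ − (L∞ − L_tm) e^(−k_A ((t + δt) − (t_m + t₀)))

anchored at its own metamorphic length `L_tm` and an individual asymptote
L∞,i ~ N(μ_L∞, σ²_L∞) truncated above its metamorphic length. Every
observed length is Normal(curve mean, σ_L²) with the observation variance
shared across stages. Priors are vague: uniforms for μ_L∞, t₀ and α,
Gamma(0.1, 0.1) (shape–rate) for the rates and variances.

The posterior is sampled with an adaptive Metropolis-within-Gibbs kernel
written for this model: componentwise random-walk updates on transformed
scales for the eight population parameters, and vectorised element-wise
updates for the hundreds of latent variables (metamorph ages, adult ages
at metamorphosis and first capture, individual asymptotes). Convergence is
assessed with classic Gelman–Rubin PSRF, the Brooks–Gelman multivariate
PSRF, and autocorrelation-based effective sample sizes; goodness of fit
with χ²-type posterior predictive (Bayesian) p-values for larval sizes
and adult growth increments.

## Worked example

Simulate a dataset with the generator defaults (asymptote 59 mm, larval
rate 1.77/yr, adult rate 0.91/yr), fit a short three-chain run, and
summarise:

```r
library(stagegrow)

sim <- simulate_dataset(sim_config(n_larvae = 200, n_metamorphs = 300,
                                   n_adults = 300, seed = 1))
fit <- run_mcmc(sim$dataset, default_priors(),
                preset_config("reduced", seed = 1))
summarize_draws(fit)
#>     parameter         mean         lo95         hi95      psrf       ess
#> 1     mu_Linf 5.901231e+01 58.725112183 59.314450990 0.9997686 1799.9625
#> 2 sigma2_Linf 5.063637e+00  4.163426950  6.083917615 0.9997501 3585.4726
#> 3    k_larval 1.795035e+00  1.748724430  1.842196834 0.9998414  718.5806
#> 4     k_adult 9.306673e-01  0.702228036  1.242834359 1.0293627  100.6936
#> 5          t0 6.131299e-04 -0.006880669  0.008274957 0.9999407  761.8938
#> 6       alpha 4.598011e+00  3.277772894  6.375746385 1.0207802  104.7438
#> 7    sigma2_t 2.799436e-01  0.168884750  0.464426178 1.0018430  215.0131
#> 8    sigma2_L 3.725293e+00  3.433083532  4.046416761 1.0002412 3169.5006
```

Every 95% credible interval covers its generating value (1.77, 0.91,
59.0, …). Derived quantities come from `compute_derived(fit)`: for this
fit, larvae on the population-mean curve reach the ~35 mm metamorphic
size in 26.17 weeks (95% CrI 25.8–26.5), and the 97.5th percentile of
the predicted adult age distribution — a longevity proxy — is 13.2
years. Diagnostics and the two posterior predictive p-values come from
`diagnostics_report(fit, sim$dataset)`.

Field data in CSV form (larval records with capture and pond-fill dates,
metamorph lengths, long-format adult capture histories) are read with
`read_larval_csv()`, `read_metamorph_csv()` and
`read_adult_captures_csv()`; `cmd_simulate()` / `cmd_fit()` /
`cmd_diagnose()` / `cmd_report()` run the same pipeline against files,
and `inst/cli/stagegrow.R` wraps them for the shell.

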