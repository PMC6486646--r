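# mrspike

Robust two-sample Mendelian randomization (MR) from GWAS summary
statistics by normal-mixture **spike detection**, with the standard
comparator estimators and a genome-scale simulator.

## The problem

MR uses genetic variants as instruments to estimate the causal effect
θ of an exposure *X* on an outcome *Y* from two GWAS. With polygenic
instrument sets, horizontal pleiotropy — direct SNP effects on the
outcome, often correlated with the exposure effects — invalidates the
classical estimators: inverse-variance weighting (IVW) is biased, and
Egger regression still needs the InSIDE assumption. `mrspike` is for
analysts who have instrument-level summary statistics (effect, SE,
sample size per SNP, pre-pruned to approximate independence) from two
studies and want an estimate that tolerates a large fraction of invalid
instruments.

## The method

Direct effects (u_x, u_y) follow a four-component mixture: valid
instruments (u_x ~ N(0, σx²), u_y = 0), correlated pleiotropy
((u_x, u_y) bivariate normal with covariance σxy), outcome-only SNPs,
and null SNPs; total effects are β_x = u_x, β_y = u_y + θ·u_x. For each
candidate θ̃ on a grid, the residuals β̂_y − θ̃·β̂_x are fit with a
constrained two-component EM,

    β̂_y − θ̃ β̂_x ~ π₀ N(0, s_y² + θ̃² s_x²) + (1 − π₀) N(0, σ²),

and the estimate is the spike-detection argmax
θ̂ = argmax_θ̃ π̂₀(θ̃): only at the true θ do the valid instruments
collapse into the known-variance null component. Standard errors come
from an estimating-equation (sandwich) construction stacking the two
score equations with the profile-maximization condition, validated
against a parametric bootstrap. IVW, Egger regression, weighted median
and weighted mode are included for comparison, and a simulator generates
genome-scale replicate studies (200,000 SNPs, normal / large-effect /
Laplace / Student-t effect families) for benchmarking.

## Worked example

A simulated two-sample study at the package defaults (200,000 SNPs,
exposure heritability 20%, half of the exposure-associated SNPs valid
instruments, correlated pleiotropy in the other half, true θ = 0.2,
n_x = n_y = 500,000):

```r
library(mrspike)

cfg <- sim_config(n_x = 5e5, C = 1, theta = 0.2, valid_frac = 0.5)
set.seed(42)
eff <- simulate_true_effects(cfg)
sim <- simulate_sumstats(eff, cfg)
nrow(sim$instruments)
#> [1] 1203

mrmix_estimate(sim$instruments)
#> Mixture-model MR (spike detection) estimate
#>   theta_hat = 0.2000  (SE 0.0063, 95% CI [0.1876, 0.2124], sandwich)
#>   pi0 at maximum = 0.5269 over 201 grid points, 1203 instruments

mr_estimate_all(sim$instruments, se_method = "none", bootstrap_B = 0)
#>            method theta_hat          se    ci_low   ci_high     intercept
#> 1           mrmix 0.2000000          NA        NA        NA            NA
#> 2             ivw 0.4223759 0.003506453 0.4155032 0.4292485            NA
#> 3           egger 0.4574638 0.050789558 0.3579162 0.5570113 -0.0004230273
#> 4 weighted_median 0.2670624          NA        NA        NA            NA
#> 5   weighted_mode 0.1874048          NA        NA        NA            NA
```

1,203 SNPs pass genome-wide significance for the exposure. The
spike-detection estimate recovers θ = 0.2 exactly (π̂₀ ≈ 0.53: about
half the selected instruments sit on the null spike, matching the 50%
valid design), while IVW and Egger are pulled to ~0.42–0.46 by the
correlated pleiotropy and the weighted median is noticeably biased; the
weighted mode is closest among the comparators, as expected since it
shares the zero-modal-pleiotropy assumption.

Real data enter through `read_sumstats()` → `harmonize_pair()` →
`standardize_effects()` → `apply_qc_filters()` → `select_instruments()`
(or in one call, `cmd_estimate()`), with allele sign-flipping,
strand-ambiguity removal, MAF/MHC/z²/sample-size QC and two-sided
z-test instrument selection at p < 5e-8 by default.

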