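---
title: "Mixture-model Mendelian randomization by spike detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model Mendelian randomization by spike detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrspike)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure $X$ on an outcome $Y$ from two independent GWAS:
for each of $M$ approximately independent SNPs we observe noisy
standardized association estimates
$\hat\beta_x \sim N(\beta_x, s_x^2)$ and
$\hat\beta_y \sim N(\beta_y, s_y^2)$ with known standard errors. If every
instrument were valid — associated with $Y$ only through $X$ — the true
coefficients would satisfy $\beta_y = \theta\beta_x$ and any ratio-based
meta-analysis would do. In polygenic data this assumption fails wholesale:
SNPs have direct (horizontally pleiotropic) effects on the outcome, often
*correlated* with their exposure effects, which biases the
inverse-variance weighted (IVW) estimator and breaks the InSIDE
assumption behind Egger regression.

## The model

`mrspike` implements a spike-detection estimator built on a four-component
bivariate normal-mixture model for the direct effects $(u_x, u_y)$, with
mixing probabilities $\pi_1,\ldots,\pi_4$:

1. valid instruments: $u_x \sim N(0, \sigma_x^2)$, $u_y = 0$;
2. correlated pleiotropy: $(u_x, u_y)$ bivariate normal with variances
   $\sigma_x^2, \sigma_y^2$ and covariance $\sigma_{xy}$ (InSIDE may be
   violated);
3. outcome-only SNPs: $u_x = 0$, $u_y \sim N(0, \sigma_y^2)$;
4. null SNPs: $u_x = u_y = 0$.

Total effects follow the structural equations $\beta_x = u_x$ and
$\beta_y = u_y + \theta u_x$. The most common pleiotropic effect is zero
(components 1 and 4), so the model implies the zero-modal-pleiotropy
(ZEMPA) assumption also underlying the weighted-mode estimator.

The key observation: at a candidate value $\tilde\theta$ the residual
$\hat\beta_y - \tilde\theta\hat\beta_x$ of a valid instrument is pure
estimation noise, $N(0, s_y^2 + \tilde\theta^2 s_x^2)$, and only at
$\tilde\theta = \theta$ do the valid and null components collapse onto
that known-variance "spike". The estimator therefore fits, at each grid
point $\tilde\theta$, the two-component working model

$$\hat\beta_y - \tilde\theta\hat\beta_x \sim
  \pi_0\,N(0,\, s_y^2 + \tilde\theta^2 s_x^2)
  + (1 - \pi_0)\,N(0, \sigma^2),$$

and takes $\hat\theta = \mathrm{argmax}_{\tilde\theta}\,
\hat\pi_0(\tilde\theta)$. The working model is correct only at the truth;
elsewhere it merely approximates the multi-component residual mixture,
which is exactly what makes $\hat\pi_0$ peak at the truth. With
overlapping study samples the null variance generalizes to
$s_y^2 + \tilde\theta^2 s_x^2 - 2\tilde\theta s_{xy}$, where $s_{xy}$ is
the covariance of the two studies' estimation errors (`s_xy` throughout
the API).

## Numerical choices

**EM with a separation constraint.** Each per-$\tilde\theta$ fit is an EM
iteration with per-SNP fixed null variances $v_j$ and a shared free
variance $\sigma^2$ constrained to
$\sigma^2 \ge (1 + 10^{-6})\max_j v_j$. Without the constraint the two
components can swap roles and $\hat\pi_0$ loses its meaning; the
$10^{-6}$ slack keeps the constraint strict without affecting genuine
fits. The M-step maximizes the complete-data likelihood over the
constraint set by projection, so the log-likelihood is monotone (a
property the tests assert on the recorded trace). Iteration stops at a
$10^{-8}$ relative log-likelihood change or 10,000 iterations.
Boundary solutions ($\pi_0 \in \{0, 1\}$), which EM approaches only
geometrically slowly (e.g. residuals identically zero), are checked
explicitly and returned when they dominate.

**Initialization and warm starts.** Cold starts use $\pi_0 = 0.5$ and
$\sigma^2 = \max(2\,\mathrm{var}(r), \text{floor})$. Along the grid each
fit is additionally warm-started from the previous point's solution, and
the better-likelihood fit is kept; this stabilizes the profile against
occasional local optima while the always-run cold start prevents a bad
warm path from propagating.

**Grid and tie-breaks.** The default grid is
$\tilde\theta \in [-1, 1]$ in steps of $0.01$ — a broad range given
standardized effects; both range and step are user-configurable, and the
grid should always bracket the plausible effect. Ties in
$\hat\pi_0$ are broken toward the smallest $|\tilde\theta|$, then the
smallest $\tilde\theta$, favoring the null. An optional golden-section
refinement within one grid step is available (`refine = TRUE`) but off by
default: the estimator is defined by the grid search. Degenerate inputs
are surfaced, not hidden: a profile whose range of $\hat\pi_0$ is below
$10^{-6}$ triggers a non-identifiability warning, fewer than 50
instruments triggers a stability warning, and a non-positive null
variance (an overlap covariance too large for the candidate slope) is an
error.

## Standard errors

The estimate jointly solves the two score equations
$\partial l/\partial\pi_0 = 0$, $\partial l/\partial\sigma^2 = 0$ of the
working likelihood and, by the implicit function theorem, the
profile-maximization condition

$$\frac{\partial^2 l}{\partial(\sigma^2)^2}
  \frac{\partial^2 l}{\partial\pi_0\,\partial\theta}
- \frac{\partial^2 l}{\partial\sigma^2\,\partial\pi_0}
  \frac{\partial^2 l}{\partial\sigma^2\,\partial\theta} = 0.$$

That last equation is a product of sums rather than a plain sum, so for
the sandwich variance the stack is augmented with two auxiliary mean
parameters (the per-SNP means of $\partial^2 l_j/\partial(\sigma^2)^2$
and $\partial^2 l_j/\partial\sigma^2\partial\pi_0$), giving five per-SNP
estimating functions with standard M-estimation asymptotics. All first
and mixed second derivatives of the per-SNP log-likelihood are analytic
(the tests verify them against central finite differences to $10^{-5}$
relative error); the bread Jacobian uses central differences of those
analytic functions with steps of $10^{-5}$ times the parameter scale. On
the standardized scale $\sigma^2$ is of order $10^{-5}$, so the bread is
equilibrated (row scaling plus column scaling of the nuisance directions,
which leaves the $(\theta,\theta)$ variance entry invariant) before
inversion. A singular bread or a boundary fit falls back to the
bootstrap with a warning.

A parametric bootstrap (`parametric_bootstrap_se()`) serves as the
validation oracle: outcome estimates are resampled from the fitted
working model at $\hat\theta$ and the full grid search is re-run per
replicate. In our simulations the sandwich agrees with the bootstrap
within its Monte-Carlo error at large exposure sample sizes and reads
10–15% below it at $n_x$ of one to two hundred thousand; the difference
is the grid-quantization and instrument-selection variability that the
bootstrap (which repeats the grid search) captures but the stacked
estimating equations, which condition on the selected instruments and
treat $\hat\theta$ as an interior root, do not. We report the sandwich as
specified rather than inflating it; users wanting the more conservative
number at moderate sample sizes can request `se_method = "bootstrap"` or
`"both"`.

## The simulator

`sim_config()` + `run_replicates()` emulate a two-sample genome-scale
design: $M = 200{,}000$ independent SNPs; component probabilities
$\pi_3 = 0.01$, $\pi_4 = 0.97$, and 2% of SNPs causal for the exposure,
split between valid and pleiotropic instruments by `valid_frac` (0.5 or
0.25 in the standard settings); $\sigma_x^2 = \sigma_y^2 = 5\times
10^{-5}$ and $\sigma_{xy} = 0.5\,\sigma_x\sigma_y$. These values give an
exposure heritability of exactly 20% and outcome heritability between
18.8% ($\theta = -0.2$, 50% valid) and 28.8% ($\theta = +0.2$, 25%
valid) — `expected_heritability()` returns the closed forms. Summary
statistics add independent noise with $s = 1/\sqrt{n}$ per study
(bivariate when `overlap_cov` is set), and instruments are selected at
two-sided $p < 5\times 10^{-8}$ on the exposure, yielding on average
about 105 instruments at $n_x = 10^5$ and about 1,135 at
$n_x = 5\times 10^5$. Per-replicate seeds are derived from the master
seed by a deterministic integer hash, so replicate $r$ is reproducible
regardless of how many replicates are requested.

Three effect-size families are provided. Scenario A is the normal model
above. Scenario B adds a rare large-effect subcomponent: with probability
`q_big` (pleiotropic SNPs) or `q_big_valid` (valid instruments; default
twice as large, so the biggest exposure effects are more often valid) a
SNP's variance is multiplied by `kappa` (default 10), and the base
variance is deflated so the marginal component variance — and hence the
heritability — is unchanged. These knobs are explicit stand-ins: they
realize the qualitative design (distinct large-effect clusters, enriched
for valid instruments) without claiming particular published values.
Scenario C swaps the normal component draws for Laplace
(scale $\sqrt{\sigma^2/2}$) or Student-$t$ (df = 5, scaled by
$\sqrt{\sigma^2(df-2)/df}$) innovations matched to the same variances;
correlated component-2 pairs use a common-factor construction that
preserves the correlation and marginal variances (the sum of two
non-normal innovations is not exactly the named family — a deliberate,
documented approximation). Replacing the families by normals recovers
Scenario A in distribution.

What the simulator does *not* emulate: linkage disequilibrium between
SNPs (the design assumes pre-pruned independent instruments), genotype-
level sampling, binary-outcome liability scales, and allele-frequency-
dependent effect sizes. Passing tests therefore demonstrate correctness
of the estimator under the stated generating model, not robustness to LD
or to selection artifacts in real consortium data.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the full genome-scale
design ($M = 200{,}000$) with 50 replicates for instrument-count
summaries, 100 replicates for bias summaries at $n_x = 5\times 10^5$ and
$10^6$, 200 replicates for interval coverage, and bootstrap sizes of
100–200; these sizes reproduce the reported quantities to within their
Monte-Carlo error while keeping a full run in the minutes range on one
CPU. The dense-grid likelihood oracle for the EM uses a
$0.005 \times$ log-spaced $(\pi_0, \sigma^2)$ grid on instances of a few
hundred residuals, where the grid resolution bounds the comparison
tolerance.

## Worked example

```{r example, eval = FALSE}
library(mrspike)

# a genome-scale replicate: effects, summary statistics, instruments
cfg <- sim_config(n_x = 5e5, C = 1, theta = 0.2, valid_frac = 0.5)
set.seed(42)
eff <- simulate_true_effects(cfg)
sim <- simulate_sumstats(eff, cfg)
nrow(sim$instruments)

# spike detection with a sandwich standard error
fit <- mrmix_estimate(sim$instruments)
fit

# the comparator estimators on the same instruments
mr_estimate_all(sim$instruments, se_method = "none", bootstrap_B = 0)
```

The same pipeline runs from files via `cmd_estimate()` (or the
`inst/cli/mrspike.R` script): read, harmonize alleles (sign-flipping
swapped orientations, dropping strand-ambiguous SNPs), standardize to
the $z/\sqrt{n}$ scale, apply QC (MAF $> 0.05$, MHC removal at
chr6:26–34 Mb, $z^2 \le 80$, per-SNP sample size at least $2/3$ of the
study's 90th percentile), select instruments, estimate. The QC defaults
follow common practice for HapMap3-type panels; selection can use an
independent study's $z$ statistics (`selection_z`) for a winner's-curse-
free three-sample design at liberal thresholds. An optional SNP
allow-list stands in for restricting to a reference panel (the package
bundles no such resource).

## Known limitations

* The causal direction matters: run both directions
  (`run_replicates(..., reverse = TRUE)` in simulations) — on
  forward-causal data the reverse estimate centers near zero, which is a
  feature, not a bug, of the spike-detection construction.
* With fewer than ~50 instruments the profile gets noisy; the package
  warns but does not refuse.
* The sandwich SE is mildly anti-conservative at moderate exposure
  sample sizes (see above); the bootstrap is the safer choice there.
* Estimates are restricted to the grid; widen or refine the grid for
  effects near its edge.
* Full maximum-likelihood fitting of the four-component bivariate model
  is out of scope by design: the two-component working model plus grid
  search is the method.
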