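#' Configuration for a genome-scale summary-statistics simulation
#'
#' Defines the generating four-component effect-size model and study
#' design. A SNP belongs to one of four components: (1) direct effect on
#' the exposure only (valid instrument), (2) correlated direct effects on
#' both traits (horizontal pleiotropy, InSIDE violated), (3) direct effect
#' on the outcome only, (4) no effect on either trait. Total effects follow
#' the structural equations \eqn{\beta_x = u_x} and
#' \eqn{\beta_y = u_y + \theta u_x}.
#'
#' Defaults reproduce the standard genome-scale design: 200,000 independent
#' SNPs, \eqn{\pi_3 = 0.01}, \eqn{\pi_4 = 0.97}, 2% of SNPs causal for the
#' exposure split between components 1 and 2 by `valid_frac`,
#' \eqn{\sigma_x^2 = \sigma_y^2 = 5\times 10^{-5}} and
#' \eqn{\sigma_{xy} = 0.5\sigma_x\sigma_y}, giving exposure heritability
#' 20%.
#'
#' @param M Number of independent SNPs (default 200,000).
#' @param theta True causal effect of X on Y (default 0.2).
#' @param valid_frac Fraction of exposure-causal SNPs that are valid
#'   instruments (default 0.5); sets `pi1 = 0.02 * valid_frac`,
#'   `pi2 = 0.02 * (1 - valid_frac)`. Ignored when `pi` is given.
#' @param pi Optional explicit mixing probabilities `c(pi1, pi2, pi3, pi4)`
#'   summing to 1.
#' @param sigma2_x,sigma2_y Direct-effect variances (default 5e-5).
#' @param rho_xy Correlation of component-2 direct effects (default 0.5);
#'   \eqn{\sigma_{xy} = \rho\sigma_x\sigma_y}.
#' @param n_x Exposure-study sample size (default 100,000).
#' @param C Ratio `n_x / n_y` (default 1; 3 models a smaller outcome
#'   study).
#' @param scenario `"A"` (normal components), `"B"` (large-effect
#'   subcomponents, with larger exposure effects more likely to be valid
#'   instruments), or `"C"` (non-normal component distributions).
#' @param scenario_options List of scenario knobs. Scenario B: `q_big`
#'   (large-effect probability for pleiotropic SNPs, default 0.01),
#'   `q_big_valid` (for valid instruments, default 0.02), `kappa`
#'   (variance multiplier, default 10); component variances are rescaled so
#'   the marginal variance stays at `sigma2_x`/`sigma2_y`. Scenario C:
#'   `dist` (`"laplace"` or `"student_t"`), `t_df` (default 5); draws are
#'   scaled to match the component variances.
#' @param overlap_cov Covariance \eqn{s_{xy}} of the two studies'
#'   estimation errors for overlapping samples (default 0).
#' @param p_threshold Instrument-selection p-value threshold (default
#'   5e-8).
#' @param three_sample Use an independent selection study for instrument
#'   selection (default `FALSE`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(M = 200000, theta = 0.2, valid_frac = 0.5, pi = NULL,
                       sigma2_x = 5e-5, sigma2_y = 5e-5, rho_xy = 0.5,
                       n_x = 100000, C = 1, scenario = c("A", "B", "C"),
                       scenario_options = list(), overlap_cov = 0,
                       p_threshold = 5e-8, three_sample = FALSE) {
  scenario <- match.arg(scenario)
  if (is.null(pi)) {
    stopifnot(valid_frac > 0, valid_frac <= 1)
    pi <- c(0.02 * valid_frac, 0.02 * (1 - valid_frac), 0.01, 0)
    pi[4] <- 1 - sum(pi[1:3])
  }
  stopifnot(length(pi) == 4, all(pi >= 0), abs(sum(pi) - 1) < 1e-8,
            M >= 1, n_x >= 1, C > 0, sigma2_x > 0, sigma2_y > 0,
            abs(rho_xy) <= 1, p_threshold > 0, p_threshold < 1)
  opts <- modifyList(
    list(q_big = 0.01, q_big_valid = 0.02, kappa = 10,
         dist = "laplace", t_df = 5),
    scenario_options)
  stopifnot(opts$kappa > 1, opts$t_df > 2)
  structure(list(M = as.integer(M), theta = theta, pi = pi,
                 sigma2_x = sigma2_x, sigma2_y = sigma2_y, rho_xy = rho_xy,
                 sigma_xy = rho_xy * sqrt(sigma2_x * sigma2_y),
                 n_x = n_x, n_y = n_x / C, C = C, scenario = scenario,
                 scenario_options = opts, overlap_cov = overlap_cov,
                 p_threshold = p_threshold, three_sample = three_sample),
            class = "sim_config")
}

# One draw of a zero-mean unit-variance innovation per scenario family.
rinnov <- function(n, config) {
  if (config$scenario == "C") {
    if (config$scenario_options$dist == "laplace") {
      # difference of exponentials; scale sqrt(1/2) gives unit variance
      (rexp(n, 1) - rexp(n, 1)) / sqrt(2)
    } else {
      df <- config$scenario_options$t_df
      rt(n, df) * sqrt((df - 2) / df)
    }
  } else {
    rnorm(n)
  }
}

# Scenario-B per-SNP effect scale: with probability q the variance is
# multiplied by kappa; the base variance is deflated so the marginal
# variance stays at sigma2.
big_effect_scale <- function(n, q, kappa) {
  base <- 1 / (1 - q + q * kappa)
  sqrt(base * ifelse(runif(n) < q, kappa, 1))
}

#' Simulate true per-SNP effect sizes
#'
#' Draws component labels multinomially and direct effects \eqn{(u_x, u_y)}
#' from the configured component distributions, then computes total effects
#' by the structural equations \eqn{\beta_x = u_x},
#' \eqn{\beta_y = u_y + \theta u_x}. Uses the current RNG state; seed the
#' generator with `set.seed()` for reproducibility.
#'
#' @param config A [sim_config()].
#' @return A list of class `true_effects` with `component` (1--4), `u_x`,
#'   `u_y`, `beta_x`, `beta_y`.
#' @export
simulate_true_effects <- function(config) {
  M <- config$M
  comp <- sample.int(4, M, replace = TRUE, prob = config$pi)
  u_x <- numeric(M)
  u_y <- numeric(M)
  sx <- sqrt(config$sigma2_x)
  sy <- sqrt(config$sigma2_y)
  rho <- config$rho_xy
  opts <- config$scenario_options

  i1 <- which(comp == 1)
  if (length(i1) > 0) {
    scale1 <- if (config$scenario == "B") {
      big_effect_scale(length(i1), opts$q_big_valid, opts$kappa)
    } else 1
    u_x[i1] <- sx * scale1 * rinnov(length(i1), config)
  }
  i2 <- which(comp == 2)
  if (length(i2) > 0) {
    n2 <- length(i2)
    scale2x <- if (config$scenario == "B") {
      big_effect_scale(n2, opts$q_big, opts$kappa)
    } else 1
    scale2y <- if (config$scenario == "B") {
      big_effect_scale(n2, opts$q_big, opts$kappa)
    } else 1
    zx <- rinnov(n2, config)
    # correlated innovation: common-factor construction keeps the target
    # correlation and marginal variances for non-normal families too
    zy <- rho * zx + sqrt(1 - rho^2) * rinnov(n2, config)
    u_x[i2] <- sx * scale2x * zx
    u_y[i2] <- sy * scale2y * zy
  }
  i3 <- which(comp == 3)
  if (length(i3) > 0) {
    scale3 <- if (config$scenario == "B") {
      big_effect_scale(length(i3), opts$q_big_valid, opts$kappa)
    } else 1
    u_y[i3] <- sy * scale3 * rinnov(length(i3), config)
  }
  structure(list(component = comp, u_x = u_x, u_y = u_y,
                 beta_x = u_x, beta_y = u_y + config$theta * u_x),
            class = "true_effects")
}

#' Closed-form expected heritability of the two traits
#'
#' For standardized effects the heritability is the expected sum of squared
#' total effects. Component-wise moment decomposition gives
#' \deqn{h_x^2 = M(\pi_1 + \pi_2)\sigma_x^2} and
#' \deqn{h_y^2 = M[\pi_2(\sigma_y^2 + \theta^2\sigma_x^2 +
#'   2\theta\sigma_{xy}) + \pi_1\theta^2\sigma_x^2 + \pi_3\sigma_y^2].}
#' The same formulas hold for all scenarios because their component
#' distributions are scaled to the same variances.
#'
#' @param config A [sim_config()].
#' @return Named vector `c(h2_x, h2_y)`.
#' @export
expected_heritability <- function(config) {
  p <- config$pi
  th <- config$theta
  h2_x <- config$M * (p[1] + p[2]) * config$sigma2_x
  h2_y <- config$M * (p[2] * (config$sigma2_y + th^2 * config$sigma2_x +
                                2 * th * config$sigma_xy) +
                        p[1] * th^2 * config$sigma2_x +
                        p[3] * config$sigma2_y)
  c(h2_x = h2_x, h2_y = h2_y)
}

#' Simulate GWAS summary statistics from true effects
#'
#' Adds estimation noise \eqn{\hat\beta_x \sim N(\beta_x, 1/n_x)},
#' \eqn{\hat\beta_y \sim N(\beta_y, 1/n_y)} (bivariate with covariance
#' `overlap_cov` when non-zero), attaches synthetic SNP identifiers,
#' positions and alleles so the full QC path can run end-to-end, and
#' selects instruments at the configured p-value threshold. In
#' `three_sample` mode an independent exposure replicate is drawn and used
#' only for selection.
#'
#' @param effects A `true_effects` object from [simulate_true_effects()].
#' @param config The matching [sim_config()].
#' @return A list with `sumstats` (full harmonized-format genome table)
#'   and `instruments` (the selected rows).
#' @export
simulate_sumstats <- function(effects, config) {
  M <- config$M
  s_x <- 1 / sqrt(config$n_x)
  s_y <- 1 / sqrt(config$n_y)
  e_x <- rnorm(M, 0, s_x)
  if (config$overlap_cov != 0) {
    a <- config$overlap_cov / s_x^2
    resid_var <- s_y^2 - a^2 * s_x^2
    if (resid_var <= 0) stop("overlap_cov too large for these sample sizes",
                             call. = FALSE)
    e_y <- a * e_x + rnorm(M, 0, sqrt(resid_var))
  } else {
    e_y <- rnorm(M, 0, s_y)
  }
  beta_x_hat <- effects$beta_x + e_x
  beta_y_hat <- effects$beta_y + e_y
  tab <- data.frame(
    snp_id = paste0("snp", seq_len(M)),
    chrom = as.character(rep_len(1:22, M)),
    pos = 1e6 + 1000 * (seq_len(M) - 1),
    ea = "A", oa = "G",
    maf = 0.25,
    beta_x = beta_x_hat, se_x = s_x, n_x = config$n_x,
    beta_y = beta_y_hat, se_y = s_y, n_y = config$n_y,
    stringsAsFactors = FALSE
  )
  tab$z_x <- tab$beta_x / tab$se_x
  tab$z_y <- tab$beta_y / tab$se_y
  selection_z <- NULL
  if (config$three_sample) {
    sel <- effects$beta_x + rnorm(M, 0, s_x)
    selection_z <- setNames(sel / s_x, tab$snp_id)
  }
  instruments <- select_instruments(tab, config$p_threshold, selection_z)
  list(sumstats = tab, instruments = instruments,
       selection_z = selection_z)
}

#' Run replicate simulation studies
#'
#' Generates `R` independent replicates (fresh effects and noise each),
#' estimates the causal effect in each with every requested method, and
#' aggregates means and standard deviations. Per-replicate seeds are
#' derived deterministically from the master seed, so replicate `r` is
#' reproducible regardless of `R`.
#'
#' @param config A [sim_config()].
#' @param methods Methods to run (see [mr_estimate_all()]); `character(0)`
#'   records instrument counts only.
#' @param R Number of replicates.
#' @param seed Master seed.
#' @param grid Grid for the mixture estimator; default
#'   `seq(-1, 1, by = 0.01)`.
#' @param se_method Standard-error method for the mixture estimator
#'   (default `"none"`: simulation summaries need only point estimates).
#' @param reverse Also estimate with the exposure and outcome roles
#'   swapped (instruments re-selected on the outcome study); reported as
#'   `<method>_rev` (default `FALSE`).
#' @return A list of class `sim_summary` with `per_replicate` (data frame:
#'   `replicate`, `n_iv`, `theta_<method>` and optionally `se_<method>`
#'   columns) and `aggregate` (data frame: `method`, `mean`, `sd`,
#'   `n_ok`, `mean_n_iv`).
#' @export
run_replicates <- function(config, methods = "mrmix", R = 100, seed = 1,
                           grid = seq(-1, 1, by = 0.01),
                           se_method = "none", reverse = FALSE) {
  stopifnot(R >= 1)
  all_methods <- if (reverse) c(methods, paste0(methods, "_rev")) else methods
  theta_cols <- paste0("theta_", all_methods)
  se_cols <- paste0("se_", all_methods)
  want_se <- !identical(se_method, "none")
  per <- data.frame(replicate = seq_len(R), n_iv = NA_real_)
  for (cc in theta_cols) per[[cc]] <- NA_real_
  if (want_se) for (cc in se_cols) per[[cc]] <- NA_real_

  estimate_one <- function(instruments, m) {
    tryCatch(suppressWarnings(suppressMessages({
      if (m == "mrmix") {
        r <- mrmix_estimate(instruments, grid = grid,
                            s_xy = config$overlap_cov,
                            se_method = se_method)
        c(r$theta_hat, r$se)
      } else {
        est <- switch(m,
          ivw = mr_ivw(instruments),
          egger = mr_egger(instruments),
          weighted_median = mr_weighted_median(instruments, bootstrap_B = 0),
          weighted_mode = mr_weighted_mode(instruments, bootstrap_B = 0),
          stop("unknown method: ", m))
        c(est$theta_hat, est$se)
      }
    })), error = function(e) c(NA_real_, NA_real_))
  }

  for (r in seq_len(R)) {
    set.seed(derive_seed(seed, r))
    eff <- simulate_true_effects(config)
    sim <- simulate_sumstats(eff, config)
    inst <- sim$instruments
    per$n_iv[r] <- nrow(inst)
    rev_inst <- NULL
    if (reverse) {
      swapped <- sim$sumstats
      names(swapped)[match(c("beta_x", "se_x", "n_x", "z_x",
                             "beta_y", "se_y", "n_y", "z_y"),
                           names(swapped))] <-
        c("beta_y", "se_y", "n_y", "z_y", "beta_x", "se_x", "n_x", "z_x")
      rev_inst <- select_instruments(swapped, config$p_threshold)
    }
    for (m in methods) {
      if (nrow(inst) >= 2) {
        val <- estimate_one(inst, m)
        per[r, paste0("theta_", m)] <- val[1]
        if (want_se) per[r, paste0("se_", m)] <- val[2]
      }
      if (reverse && !is.null(rev_inst) && nrow(rev_inst) >= 2) {
        val <- estimate_one(rev_inst, m)
        per[r, paste0("theta_", m, "_rev")] <- val[1]
        if (want_se) per[r, paste0("se_", m, "_rev")] <- val[2]
      }
    }
  }
  agg <- do.call(rbind, lapply(all_methods, function(m) {
    th <- per[[paste0("theta_", m)]]
    data.frame(method = m, mean = mean(th, na.rm = TRUE),
               sd = sd(th, na.rm = TRUE), n_ok = sum(!is.na(th)),
               mean_n_iv = mean(per$n_iv), stringsAsFactors = FALSE)
  }))
  structure(list(per_replicate = per, aggregate = agg, config = config,
                 seed = seed),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf(
    "Simulation summary: scenario %s, theta = %g, M = %d, n_x = %g, C = %g\n",
    x$config$scenario, x$config$theta, x$config$M, x$config$n_x,
    x$config$C))
  cat(sprintf("%d replicates, mean instrument count %.1f\n",
              nrow(x$per_replicate), mean(x$per_replicate$n_iv)))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
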