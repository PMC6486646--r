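# Benchmark polygenic MR estimators: inverse-variance weighted meta-analysis
# of ratio estimates, Egger regression, weighted median, and weighted mode.
# All take the same harmonized instrument table as mrmix_estimate().

new_mr_estimate <- function(method, theta_hat, se, intercept = NA_real_,
                            extra = list()) {
  structure(c(list(method = method, theta_hat = theta_hat, se = se,
                   intercept = intercept,
                   ci95 = c(theta_hat - 1.96 * se, theta_hat + 1.96 * se)),
              extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: theta_hat = %.4f", x$method, x$theta_hat))
  if (is.finite(x$se)) {
    cat(sprintf(" (SE %.4f, 95%% CI [%.4f, %.4f])", x$se, x$ci95[1],
                x$ci95[2]))
  }
  cat("\n")
  invisible(x)
}

ratio_weights <- function(instruments, weighting = c("first", "second")) {
  weighting <- match.arg(weighting)
  bx <- instruments$beta_x
  v <- instruments$se_y^2 / bx^2
  if (weighting == "second") {
    v <- v + instruments$beta_y^2 * instruments$se_x^2 / bx^4
  }
  1 / v
}

#' Inverse-variance weighted estimator
#'
#' Fixed-effect meta-analysis of the per-SNP ratio estimates:
#' \eqn{\hat\theta = \sum_j w_j\hat\beta_{x,j}\hat\beta_{y,j} /
#' \sum_j w_j\hat\beta_{x,j}^2} with \eqn{w_j = 1/s_{y,j}^2}, and
#' \eqn{SE = (\sum_j w_j \hat\beta_{x,j}^2)^{-1/2}}. Efficient when all
#' instruments are valid; biased otherwise.
#'
#' @param instruments Data frame with `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @return An object of class `mr_estimate`.
#' @export
mr_ivw <- function(instruments) {
  bx <- instruments$beta_x
  by <- instruments$beta_y
  if (all(bx == 0)) stop("all exposure effects are zero", call. = FALSE)
  w <- 1 / instruments$se_y^2
  denom <- sum(w * bx^2)
  theta <- sum(w * bx * by) / denom
  new_mr_estimate("ivw", theta, 1 / sqrt(denom))
}

#' Egger regression estimator
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept absorbing average directional pleiotropy (valid under the
#' InSIDE assumption). Instruments are first oriented so every exposure
#' effect is non-negative (flipping the paired outcome effect's sign),
#' the standard convention making the fit invariant to the arbitrary
#' stored allele orientation. Weights are \eqn{1/s_y^2}; the slope
#' standard error uses a residual dispersion floored at 1 (multiplicative
#' random effects).
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with the pleiotropy `intercept` filled in.
#' @export
mr_egger <- function(instruments) {
  if (nrow(instruments) < 3) {
    stop("Egger regression requires at least 3 instruments", call. = FALSE)
  }
  s <- ifelse(instruments$beta_x < 0, -1, 1)
  bx <- s * instruments$beta_x
  by <- s * instruments$beta_y
  if (length(unique(bx)) < 2) {
    stop("degenerate design: all exposure effects equal", call. = FALSE)
  }
  w <- 1 / instruments$se_y^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- max(sm$sigma, 1)
  se_unit <- sm$coefficients["bx", "Std. Error"] / sm$sigma
  new_mr_estimate("egger", coef(fit)[["bx"]], se_unit * disp,
                  intercept = coef(fit)[["(Intercept)"]])
}

# Weighted median of values x with positive weights w: sort, form midpoint
# cumulative probabilities p_j = (S_j - w_j/2)/S_n, and linearly interpolate
# the quantile function at 1/2.
weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  n <- length(x)
  if (0.5 >= p[n]) return(x[n])
  k <- max(which(p < 0.5))
  x[k] + (0.5 - p[k]) / (p[k + 1] - p[k]) * (x[k + 1] - x[k])
}

drop_zero_bx <- function(instruments) {
  zero <- instruments$beta_x == 0
  if (any(zero)) {
    warning(sum(zero), " instrument(s) with zero exposure effect excluded",
            call. = FALSE)
    instruments <- instruments[!zero, , drop = FALSE]
  }
  instruments
}

comparator_bootstrap_se <- function(instruments, point_fun, B, seed) {
  if (B <= 0) return(NA_real_)
  K <- nrow(instruments)
  est <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    boot <- instruments
    boot$beta_x <- rnorm(K, instruments$beta_x, instruments$se_x)
    boot$beta_y <- rnorm(K, instruments$beta_y, instruments$se_y)
    est[b] <- point_fun(boot)
  }
  sd(est)
}

#' Weighted-median estimator
#'
#' The weighted median of the per-SNP ratio estimates
#' \eqn{\hat\beta_{y,j}/\hat\beta_{x,j}}, consistent when at least half of
#' the weight comes from valid instruments. Weights are inverse
#' delta-method variances of the ratios: first-order
#' \eqn{s_y^2/\hat\beta_x^2} (default) or second-order
#' \eqn{s_y^2/\hat\beta_x^2 + \hat\beta_y^2 s_x^2/\hat\beta_x^4}. The
#' standard error is by parametric bootstrap (resampling both studies'
#' estimates from their sampling distributions).
#'
#' @inheritParams mr_ivw
#' @param weighting `"first"` or `"second"` order delta-method weights.
#' @param bootstrap_B Bootstrap replicates for the standard error (default
#'   1000; 0 skips it).
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(instruments, weighting = c("first", "second"),
                               bootstrap_B = 1000, seed = 1) {
  weighting <- match.arg(weighting)
  if (nrow(instruments) < 2) stop("need at least 2 instruments",
                                  call. = FALSE)
  instruments <- drop_zero_bx(instruments)
  point <- function(d) {
    d <- d[d$beta_x != 0, , drop = FALSE]
    weighted_median_value(d$beta_y / d$beta_x, ratio_weights(d, weighting))
  }
  se <- suppressWarnings(
    comparator_bootstrap_se(instruments, point, bootstrap_B, seed))
  new_mr_estimate("weighted_median", point(instruments), se)
}

# Weighted kernel-density argmax of the ratio estimates on a fine grid.
weighted_mode_value <- function(th, w, phi, n_grid = 512) {
  w <- w / sum(w)
  spread <- min(sd(th), mad(th))
  if (!is.finite(spread) || spread == 0) spread <- max(sd(th), mad(th))
  if (!is.finite(spread) || spread == 0) return(th[1])  # all ratios equal
  h <- phi * 0.9 * spread * length(th)^(-1 / 5)
  grid <- seq(min(th) - 3 * h, max(th) + 3 * h, length.out = n_grid)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, th, h)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' The mode of the kernel-smoothed weighted distribution of the per-SNP
#' ratio estimates, consistent under the zero-modal-pleiotropy assumption:
#' the largest group of instruments sharing a ratio value identifies the
#' causal effect. A normal kernel is used with bandwidth
#' \eqn{h = \phi \times 0.9\min(\mathrm{sd}, \mathrm{mad}) K^{-1/5}}
#' (a modified Silverman rule on the ratio distribution); the density is
#' evaluated on a 512-point grid spanning the ratios plus three bandwidths.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier (default 1).
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(instruments, phi = 1,
                             weighting = c("first", "second"),
                             bootstrap_B = 1000, seed = 1) {
  weighting <- match.arg(weighting)
  if (nrow(instruments) < 2) stop("need at least 2 instruments",
                                  call. = FALSE)
  instruments <- drop_zero_bx(instruments)
  point <- function(d) {
    d <- d[d$beta_x != 0, , drop = FALSE]
    weighted_mode_value(d$beta_y / d$beta_x, ratio_weights(d, weighting),
                        phi)
  }
  se <- suppressWarnings(
    comparator_bootstrap_se(instruments, point, bootstrap_B, seed))
  new_mr_estimate("weighted_mode", point(instruments), se)
}

#' Run a set of MR estimators on one instrument table
#'
#' @param instruments Harmonized instrument data frame.
#' @param methods Subset of `c("mrmix", "ivw", "egger", "weighted_median",
#'   "weighted_mode")`.
#' @param grid,s_xy Passed to [mrmix_estimate()].
#' @param se_method Standard-error method for the mixture estimator
#'   (`"none"` skips it, useful in simulations).
#' @param bootstrap_B,seed Bootstrap settings for median/mode standard
#'   errors (`bootstrap_B = 0` skips them).
#' @param phi Bandwidth multiplier for the weighted mode.
#' @return A data frame with one row per method: `method`, `theta_hat`,
#'   `se`, `ci_low`, `ci_high`, `intercept`.
#' @export
mr_estimate_all <- function(instruments,
                            methods = c("mrmix", "ivw", "egger",
                                        "weighted_median", "weighted_mode"),
                            grid = seq(-1, 1, by = 0.01), s_xy = 0,
                            se_method = "sandwich", bootstrap_B = 0,
                            seed = 1, phi = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- lapply(methods, function(m) {
    est <- switch(m,
      mrmix = {
        r <- mrmix_estimate(instruments, grid = grid, s_xy = s_xy,
                            se_method = se_method)
        new_mr_estimate("mrmix", r$theta_hat, r$se)
      },
      ivw = mr_ivw(instruments),
      egger = mr_egger(instruments),
      weighted_median = mr_weighted_median(instruments,
                                           bootstrap_B = bootstrap_B,
                                           seed = seed),
      weighted_mode = mr_weighted_mode(instruments, phi = phi,
                                       bootstrap_B = bootstrap_B,
                                       seed = seed))
    data.frame(method = est$method, theta_hat = est$theta_hat, se = est$se,
               ci_low = est$ci95[1], ci_high = est$ci95[2],
               intercept = est$intercept, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
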