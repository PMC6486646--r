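#' Null-component variance of the residual at a candidate causal effect
#'
#' For the residual \eqn{\hat\beta_y - \tilde\theta \hat\beta_x} of a SNP
#' with standard errors \eqn{s_x, s_y}, the sampling variance under the
#' null (valid-instrument) component is
#' \eqn{s_y^2 + \tilde\theta^2 s_x^2 - 2\tilde\theta s_{xy}}, where
#' \eqn{s_{xy}} is the covariance of the two studies' estimation errors
#' (non-zero only under sample overlap).
#'
#' @param s_x,s_y Standard errors (positive; vectorized).
#' @param theta_tilde Candidate causal effect.
#' @param s_xy Overlap covariance of estimation errors (default 0).
#' @return The null variance(s); an error if any result is non-positive.
#' @export
null_variance <- function(s_x, s_y, theta_tilde, s_xy = 0) {
  stopifnot(all(s_x > 0), all(s_y > 0))
  v <- s_y^2 + theta_tilde^2 * s_x^2 - 2 * theta_tilde * s_xy
  if (any(v <= 0)) {
    stop("non-positive null variance: overlap covariance s_xy is invalid ",
         "at theta_tilde = ", theta_tilde, call. = FALSE)
  }
  v
}

#' Constrained two-component EM fit of the residual distribution
#'
#' Fits \eqn{r_j \sim \pi_0 N(0, v_j) + (1-\pi_0) N(0, \sigma^2)} by EM,
#' where the per-SNP null variances \eqn{v_j} are fixed and known and the
#' free-component variance is shared across SNPs and constrained to
#' \eqn{\sigma^2 \ge (1+\epsilon)\max_j v_j} so the two components cannot
#' swap roles. The E-step computes posterior null responsibilities; the
#' M-step sets \eqn{\pi_0} to the mean responsibility and \eqn{\sigma^2} to
#' the responsibility-weighted second moment of the free component,
#' projected onto the constraint. Iteration stops when the relative change
#' in log-likelihood falls below `tol`. Boundary solutions
#' (\eqn{\pi_0 \in \{0, 1\}}), which EM approaches only geometrically
#' slowly, are checked explicitly and returned when they attain higher
#' likelihood.
#'
#' @param residuals Numeric vector \eqn{r_j} (at least 2).
#' @param null_vars Per-SNP null variances \eqn{v_j > 0} (length 1 or
#'   `length(residuals)`).
#' @param init Optional `c(pi0, sigma2)` initial values; default
#'   \eqn{\pi_0 = 0.5}, \eqn{\sigma^2 = \max(2\,\mathrm{var}(r),
#'   \mathrm{floor})}.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 10000); if reached, the
#'   fit is returned with `converged = FALSE`.
#' @param eps Constraint slack \eqn{\epsilon} (default 1e-6).
#' @param trace Record the per-iteration log-likelihood (default `FALSE`).
#' @return An object of class `working_mixture_fit`: a list with
#'   `pi0_hat`, `sigma2_hat`, `loglik`, `n_iter`, `converged`, and
#'   optionally `loglik_trace`.
#' @export
em_fit_two_component <- function(residuals, null_vars, init = NULL,
                                 tol = 1e-8, max_iter = 10000, eps = 1e-6,
                                 trace = FALSE) {
  n <- length(residuals)
  if (n < 2) stop("need at least 2 residuals", call. = FALSE)
  null_vars <- rep_len(null_vars, n)
  if (any(null_vars <= 0)) stop("null variances must be positive",
                                call. = FALSE)
  floor_ <- (1 + eps) * max(null_vars)
  if (is.null(init)) {
    init <- c(0.5, max(2 * var(residuals), floor_))
  }
  fit <- .em_fit_cpp(residuals, null_vars, init[1], max(init[2], floor_),
                     eps, tol, max_iter, trace)
  fit$theta_tilde <- NA_real_
  if (!fit$converged) {
    warning("EM reached max_iter = ", max_iter, " without converging",
            call. = FALSE)
  }
  structure(fit, class = "working_mixture_fit")
}

#' Profile of the null-component mass over a grid of candidate effects
#'
#' For each candidate \eqn{\tilde\theta} in the grid, fits the constrained
#' two-component mixture to the residuals
#' \eqn{\hat\beta_y - \tilde\theta\hat\beta_x} with null variances
#' \eqn{s_y^2 + \tilde\theta^2 s_x^2 - 2\tilde\theta s_{xy}}. Each fit is
#' warm-started from the previous grid point's solution (stabilizing the
#' profile) with a cold-started fit retained instead whenever it attains a
#' higher likelihood.
#'
#' @param instruments Data frame with columns `beta_x`, `se_x`, `beta_y`,
#'   `se_y` (at least 2 rows).
#' @param grid Sorted numeric vector of candidate causal effects.
#' @param s_xy Overlap covariance (default 0).
#' @inheritParams em_fit_two_component
#' @return A data frame of class `pi0_profile` with one row per grid point:
#'   `theta_tilde`, `pi0_hat`, `sigma2_hat`, `loglik`, `n_iter`,
#'   `converged`.
#' @export
pi0_profile <- function(instruments, grid, s_xy = 0, tol = 1e-8,
                        max_iter = 10000, eps = 1e-6) {
  if (length(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be sorted and strictly increasing", call. = FALSE)
  }
  if (nrow(instruments) < 2) {
    stop("need at least 2 instruments", call. = FALSE)
  }
  stopifnot(all(instruments$se_x > 0), all(instruments$se_y > 0))
  prof <- .pi0_profile_cpp(instruments$beta_x, instruments$beta_y,
                           instruments$se_x^2, instruments$se_y^2, s_xy,
                           as.numeric(grid), eps, tol, max_iter)
  class(prof) <- c("pi0_profile", "data.frame")
  prof
}

#' Causal-effect estimation by spike detection (MRMix)
#'
#' Estimates the causal effect of an exposure on an outcome from
#' harmonized, standardized instrument-level summary statistics. For each
#' candidate effect \eqn{\tilde\theta} on a grid, the residuals
#' \eqn{\hat\beta_y - \tilde\theta\hat\beta_x} are fit with a
#' two-component normal mixture whose null component has the known
#' sampling variance; the estimate is the grid point maximizing the fitted
#' null-component mass, \eqn{\hat\theta =
#' \mathrm{argmax}_{\tilde\theta}\,\hat\pi_0(\tilde\theta)}. Ties are
#' broken toward the smallest \eqn{|\tilde\theta|}, then the smallest
#' \eqn{\tilde\theta}. Optionally the argmax is refined by golden-section
#' search within one grid step.
#'
#' @inheritParams pi0_profile
#' @param grid Candidate causal effects; default `seq(-1, 1, by = 0.01)`,
#'   a broad range for standardized effects.
#' @param se_method `"sandwich"` (estimating-equation sandwich standard
#'   error, the default), `"bootstrap"`, `"both"`, or `"none"`.
#' @param refine Refine the argmax continuously within one grid step
#'   (default `FALSE`; the estimator is defined by the grid search).
#' @param boot_B,boot_seed Replicates and seed for the bootstrap standard
#'   error when requested.
#' @return An object of class `mrmix_result`: a list with `theta_hat`,
#'   `se`, `se_method`, `pi0_at_max`, `sigma2_at_max`, `profile` (the
#'   [pi0_profile()] data frame), `grid`, `n_snps`, `converged`, and
#'   `se_bootstrap` when both standard errors were computed.
#' @export
mrmix_estimate <- function(instruments, grid = seq(-1, 1, by = 0.01),
                           s_xy = 0,
                           se_method = c("sandwich", "bootstrap", "both",
                                         "none"),
                           refine = FALSE, boot_B = 200, boot_seed = 1,
                           tol = 1e-8, max_iter = 10000, eps = 1e-6) {
  se_method <- match.arg(se_method)
  if (nrow(instruments) < 50) {
    warning("fewer than 50 instruments (", nrow(instruments),
            "); the spike-detection estimator may be unstable",
            call. = FALSE)
  }
  prof <- pi0_profile(instruments, grid, s_xy = s_xy, tol = tol,
                      max_iter = max_iter, eps = eps)
  if (max(prof$pi0_hat) - min(prof$pi0_hat) < 1e-6) {
    warning("pi0 profile is flat: causal effect is not identified ",
            "from these instruments", call. = FALSE)
  }
  best <- which(prof$pi0_hat == max(prof$pi0_hat))
  if (length(best) > 1) {
    best <- best[order(abs(prof$theta_tilde[best]),
                       prof$theta_tilde[best])][1]
  }
  theta_hat <- prof$theta_tilde[best]
  pi0_at_max <- prof$pi0_hat[best]
  sigma2_at_max <- prof$sigma2_hat[best]
  converged <- prof$converged[best]

  if (refine) {
    step <- if (length(grid) > 1) max(diff(grid)) else 0
    if (step > 0) {
      ref <- refine_argmax(instruments, theta_hat - step, theta_hat + step,
                           s_xy, c(pi0_at_max, sigma2_at_max), tol, max_iter,
                           eps)
      if (ref$pi0 >= pi0_at_max) {
        theta_hat <- ref$theta
        pi0_at_max <- ref$pi0
        sigma2_at_max <- ref$sigma2
      }
    }
  }

  out <- structure(
    list(theta_hat = theta_hat, se = NA_real_, se_method = se_method,
         pi0_at_max = pi0_at_max, sigma2_at_max = sigma2_at_max,
         profile = prof, grid = as.numeric(grid), s_xy = s_xy,
         n_snps = nrow(instruments), converged = converged),
    class = "mrmix_result")
  if (se_method %in% c("sandwich", "both")) {
    out$se <- sandwich_se(out, instruments, s_xy = s_xy)
  }
  if (se_method %in% c("bootstrap", "both")) {
    se_b <- parametric_bootstrap_se(instruments, out, B = boot_B,
                                    seed = boot_seed, grid = grid,
                                    s_xy = s_xy)
    if (se_method == "bootstrap") out$se <- se_b else out$se_bootstrap <- se_b
  }
  out
}

# Golden-section maximization of pi0(theta) on [lo, hi]; each evaluation is a
# warm-started constrained EM fit at that theta.
refine_argmax <- function(instruments, lo, hi, s_xy, warm, tol, max_iter,
                          eps) {
  gr <- (sqrt(5) - 1) / 2
  f <- function(th) {
    v <- null_variance(instruments$se_x, instruments$se_y, th, s_xy)
    r <- instruments$beta_y - th * instruments$beta_x
    fit <- em_fit_two_component(r, v, init = warm, tol = tol,
                                max_iter = max_iter, eps = eps)
    list(pi0 = fit$pi0_hat, sigma2 = fit$sigma2_hat)
  }
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (i in 1:40) {
    if (b - a < 1e-6) break
    if (f1$pi0 >= f2$pi0) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  if (f1$pi0 >= f2$pi0) list(theta = c1, pi0 = f1$pi0, sigma2 = f1$sigma2)
  else list(theta = c2, pi0 = f2$pi0, sigma2 = f2$sigma2)
}

#' @export
print.mrmix_result <- function(x, ...) {
  cat("Mixture-model MR (spike detection) estimate\n")
  cat(sprintf("  theta_hat = %.4f", x$theta_hat))
  if (!is.na(x$se)) {
    cat(sprintf("  (SE %.4f, 95%% CI [%.4f, %.4f], %s)",
                x$se, x$theta_hat - 1.96 * x$se, x$theta_hat + 1.96 * x$se,
                x$se_method))
  }
  cat("\n")
  cat(sprintf("  pi0 at maximum = %.4f over %d grid points, %d instruments\n",
              x$pi0_at_max, nrow(x$profile), x$n_snps))
  invisible(x)
}
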