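# Per-SNP first and mixed second partial derivatives of the two-component
# working log-likelihood
#   l_j = log[ pi0 N(r_j; 0, v_j(theta)) + (1 - pi0) N(r_j; 0, sigma2) ],
# with r_j = beta_y - theta beta_x and
# v_j(theta) = s_y^2 + theta^2 s_x^2 - 2 theta s_xy.  Everything below is
# vectorized over SNPs; U = f0/m and W = f1/m are the component densities
# scaled by the mixture density.
loglik_partials <- function(theta, pi0, sigma2, bx, by, sx2, sy2, s_xy = 0) {
  r <- by - theta * bx
  v <- sy2 + theta^2 * sx2 - 2 * theta * s_xy
  if (any(v <= 0)) stop("non-positive null variance", call. = FALSE)
  vth <- 2 * theta * sx2 - 2 * s_xy
  lf0 <- dnorm(r, 0, sqrt(v), log = TRUE)
  lf1 <- dnorm(r, 0, sqrt(sigma2), log = TRUE)
  la <- log(pi0) + lf0
  lb <- log1p(-pi0) + lf1
  lm <- pmax(la, lb) + log1p(exp(-abs(la - lb)))
  U <- exp(lf0 - lm)
  W <- exp(lf1 - lm)
  u <- pi0 * U                      # null responsibility
  w <- (1 - pi0) * W
  k <- (r^2 - sigma2) / (2 * sigma2^2)     # d log f1 / d sigma2
  kp <- -r^2 / sigma2^3 + 1 / (2 * sigma2^2)
  kth <- -bx * r / sigma2^2
  g0 <- -vth / (2 * v) + bx * r / v + r^2 * vth / (2 * v^2)
  g1 <- bx * r / sigma2
  gbar <- u * g0 + w * g1           # d l / d theta
  psi1 <- U - W                     # d l / d pi0
  psi2 <- w * k                     # d l / d sigma2
  list(
    psi1 = psi1,
    psi2 = psi2,
    dl_dtheta = gbar,
    d2_s2s2 = (1 - pi0) * W * (k^2 + kp) - psi2^2,
    d2_pi_th = U * g0 - W * g1 - (U - W) * gbar,
    d2_s2_pi = -W * k * (1 + (1 - pi0) * (U - W)),
    d2_s2_th = w * ((g1 - gbar) * k + kth),
    loglik = sum(lm)
  )
}

# Refit the constrained mixture at a fixed theta, returning (pi0, sigma2)
# satisfying the two score equations there.
fit_at_theta <- function(instruments, theta, s_xy = 0, init = NULL,
                         tol = 1e-10, max_iter = 50000) {
  v <- null_variance(instruments$se_x, instruments$se_y, theta, s_xy)
  r <- instruments$beta_y - theta * instruments$beta_x
  suppressWarnings(
    em_fit_two_component(r, v, init = init, tol = tol, max_iter = max_iter)
  )
}

#' Estimating function whose root defines the spike-detection estimate
#'
#' The causal-effect estimate maximizes the profiled null mass
#' \eqn{\hat\pi_0(\theta)}, which (by the implicit function theorem applied
#' to the two score equations \eqn{\partial l/\partial\pi_0 = 0},
#' \eqn{\partial l/\partial\sigma^2 = 0}) is equivalent to a root of
#' \deqn{\frac{\partial^2 l}{\partial(\sigma^2)^2}
#'       \frac{\partial^2 l}{\partial\pi_0\partial\theta} -
#'       \frac{\partial^2 l}{\partial\sigma^2\partial\pi_0}
#'       \frac{\partial^2 l}{\partial\sigma^2\partial\theta} = 0,}
#' evaluated at the profiled \eqn{(\hat\pi_0(\theta),
#' \hat\sigma^2(\theta))}.
#'
#' @param instruments Data frame with `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @param theta Causal-effect value at which to evaluate.
#' @param s_xy Overlap covariance (default 0).
#' @param pi0,sigma2 Optional profiled values at `theta`; refit by EM when
#'   omitted.
#' @return The value of the estimating function (sum scale).
#' @export
estimating_function <- function(instruments, theta, s_xy = 0, pi0 = NULL,
                                sigma2 = NULL) {
  if (is.null(pi0) || is.null(sigma2)) {
    fit <- fit_at_theta(instruments, theta, s_xy)
    pi0 <- fit$pi0_hat
    sigma2 <- fit$sigma2_hat
  }
  pp <- loglik_partials(theta, pi0, sigma2, instruments$beta_x,
                        instruments$beta_y, instruments$se_x^2,
                        instruments$se_y^2, s_xy)
  val <- sum(pp$d2_s2s2) * sum(pp$d2_pi_th) -
    sum(pp$d2_s2_pi) * sum(pp$d2_s2_th)
  if (!is.finite(val)) stop("non-finite partial derivatives", call. = FALSE)
  val
}

#' Sandwich standard error of the spike-detection estimate
#'
#' Standard error by M-estimation stacking. The estimator jointly solves
#' the two score equations in \eqn{(\pi_0, \sigma^2)} and the
#' profile-maximization equation in \eqn{\theta} (see
#' [estimating_function()]). Because the latter is a product of sums, two
#' auxiliary mean parameters (the per-SNP means of
#' \eqn{\partial^2 l_j/\partial(\sigma^2)^2} and
#' \eqn{\partial^2 l_j/\partial\sigma^2\partial\pi_0}) are stacked
#' alongside, giving five per-SNP estimating functions with standard
#' sandwich asymptotics. The bread is the Jacobian of the mean estimating
#' functions (analytic derivatives differenced centrally in
#' \eqn{(\pi_0, \sigma^2, \theta)}; the auxiliary directions are exact) and
#' the meat the empirical second-moment matrix; the returned standard error
#' is the square root of the \eqn{(\theta,\theta)} entry of
#' bread\eqn{^{-1}} meat bread\eqn{^{-T}} / M.
#'
#' If the bread matrix is numerically singular, or the fitted null mass
#' sits on the boundary of \eqn{[0, 1]} (where the score equations
#' degenerate), the function falls back to [parametric_bootstrap_se()] with
#' a warning.
#'
#' @param result An `mrmix_result` from [mrmix_estimate()].
#' @param instruments The instrument data frame the result was fit on.
#' @param s_xy Overlap covariance (default taken from the result).
#' @param fallback_B,fallback_seed Bootstrap settings used only on
#'   fallback.
#' @return The standard error (positive scalar).
#' @export
sandwich_se <- function(result, instruments, s_xy = result$s_xy,
                        fallback_B = 200, fallback_seed = 1) {
  theta <- result$theta_hat
  pi0 <- result$pi0_at_max
  sigma2 <- result$sigma2_at_max
  M <- nrow(instruments)
  bx <- instruments$beta_x; by <- instruments$beta_y
  sx2 <- instruments$se_x^2; sy2 <- instruments$se_y^2

  if (pi0 >= 1 - 1e-9 || pi0 <= 1e-9) {
    warning("null-component mass on the boundary; falling back to the ",
            "bootstrap standard error", call. = FALSE)
    return(parametric_bootstrap_se(instruments, result, B = fallback_B,
                                   seed = fallback_seed))
  }

  pp0 <- loglik_partials(theta, pi0, sigma2, bx, by, sx2, sy2, s_xy)
  m_a <- mean(pp0$d2_s2s2)
  m_c <- mean(pp0$d2_s2_pi)

  psi_means <- function(p) {
    pp <- loglik_partials(p[3], p[1], p[2], bx, by, sx2, sy2, s_xy)
    c(mean(pp$psi1), mean(pp$psi2),
      m_a * mean(pp$d2_pi_th) - m_c * mean(pp$d2_s2_th),
      mean(pp$d2_s2s2) - m_a, mean(pp$d2_s2_pi) - m_c)
  }
  p0 <- c(pi0, sigma2, theta)
  h <- 1e-5 * c(1, sigma2, 1)
  A <- matrix(0, 5, 5)
  for (l in 1:3) {
    pp_ <- p0; pm_ <- p0
    pp_[l] <- pp_[l] + h[l]
    pm_[l] <- pm_[l] - h[l]
    A[, l] <- (psi_means(pp_) - psi_means(pm_)) / (2 * h[l])
  }
  A[3, 4] <- mean(pp0$d2_pi_th)
  A[3, 5] <- -mean(pp0$d2_s2_th)
  A[4, 4] <- -1
  A[5, 5] <- -1

  psi <- cbind(pp0$psi1, pp0$psi2,
               m_a * pp0$d2_pi_th - m_c * pp0$d2_s2_th,
               pp0$d2_s2s2 - m_a, pp0$d2_s2_pi - m_c)
  B <- crossprod(psi) / M

  # Equilibrate: on the standardized scale sigma2 is ~1e-5, so raw bread
  # entries span many orders of magnitude. Row scaling D and column scaling
  # S of the nuisance directions leave the (theta, theta) entry of
  # A^-1 B A^-T invariant (S[3,3] = 1) while making the solve
  # well-conditioned.
  D <- 1 / pmax(apply(abs(A), 1, max), 1e-300)
  As <- A * D
  S <- 1 / pmax(apply(abs(As), 2, max), 1e-300)
  S[3] <- 1
  As <- sweep(As, 2, S, `*`)
  Bs <- (D %o% D) * B
  Ainv <- tryCatch(solve(As), error = function(e) NULL)
  if (is.null(Ainv)) {
    warning("singular bread matrix; falling back to the bootstrap ",
            "standard error", call. = FALSE)
    return(parametric_bootstrap_se(instruments, result, B = fallback_B,
                                   seed = fallback_seed))
  }
  V <- Ainv %*% Bs %*% t(Ainv) / M
  se <- sqrt(V[3, 3])
  if (!is.finite(se) || se <= 0) {
    warning("degenerate sandwich variance; falling back to the bootstrap ",
            "standard error", call. = FALSE)
    return(parametric_bootstrap_se(instruments, result, B = fallback_B,
                                   seed = fallback_seed))
  }
  se
}

#' Parametric-bootstrap standard error
#'
#' Resamples outcome effect estimates from the fitted two-component working
#' model at the point estimate -- with probability \eqn{\hat\pi_0} a SNP's
#' residual is drawn from the null component \eqn{N(0, v_j(\hat\theta))},
#' otherwise from \eqn{N(0, \hat\sigma^2)} -- holding the exposure
#' estimates and all per-SNP standard errors fixed, re-runs the full grid
#' search on each replicate, and returns the standard deviation of the
#' replicate estimates. Replicates whose grid fit does not converge are
#' dropped and counted; more than 20% failures is an error.
#'
#' @param instruments Instrument data frame.
#' @param fit An `mrmix_result` from [mrmix_estimate()].
#' @param B Number of bootstrap replicates (at least 50).
#' @param seed Master seed; each replicate uses a seed derived
#'   deterministically from it, so results are reproducible.
#' @param grid,s_xy Grid and overlap covariance (defaults from the fit).
#' @return The bootstrap standard error, with attribute `n_failed`.
#' @export
parametric_bootstrap_se <- function(instruments, fit, B = 200, seed = 1,
                                    grid = fit$grid, s_xy = fit$s_xy) {
  if (B < 50) stop("bootstrap requires B >= 50 replicates", call. = FALSE)
  theta <- fit$theta_hat
  pi0 <- fit$pi0_hat %||% fit$pi0_at_max
  sigma2 <- fit$sigma2_hat %||% fit$sigma2_at_max
  v <- null_variance(instruments$se_x, instruments$se_y, theta, s_xy)
  K <- nrow(instruments)
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    is_null <- runif(K) < pi0
    sdv <- sqrt(ifelse(is_null, v, sigma2))
    boot <- instruments
    boot$beta_y <- theta * instruments$beta_x + rnorm(K, 0, sdv)
    res <- tryCatch(
      suppressWarnings(mrmix_estimate(boot, grid = grid, s_xy = s_xy,
                                      se_method = "none")),
      error = function(e) NULL)
    if (!is.null(res) && isTRUE(res$converged)) est[b] <- res$theta_hat
  }
  n_failed <- sum(is.na(est))
  if (n_failed > 0.2 * B) {
    stop("more than 20% of bootstrap replicates failed (", n_failed, "/",
         B, ")", call. = FALSE)
  }
  se <- sd(est, na.rm = TRUE)
  attr(se, "n_failed") <- n_failed
  se
}
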