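#' Linear-growth constants of the right-hand sides
#'
#' The quadratic-growth bounds \eqn{|F_i|^2 \le k_i (1 + |x_i|^2)} hold with
#' \deqn{k_1 = 4\left(\alpha_1^2 + \frac{\alpha_1^2}{K_1^2} M_1 +
#'   \beta_1^2 M_2 + \varepsilon^2\gamma^2\right), \qquad
#'   k_2 = 4\left(\alpha_2^2 + \frac{\alpha_2^2}{K_2^2} M_3 +
#'   \beta_2^2 M_4 + \gamma^2\right),}
#' where the \eqn{M_i} are sup bounds of the squared state components over the
#' horizon. The ten sup slots of the derivation collapse onto two scalars, one
#' per component (\code{M_healthy} bounds \eqn{\sup|x_1|^2},
#' \code{M_malignant} bounds \eqn{\sup|x_2|^2}); the defaults are the
#' invariant-region values \eqn{K_1^2, K_2^2}.
#'
#' @param params a \code{\link{tumor_params}} object.
#' @param M_healthy sup bound on \eqn{|x_1|^2} (default \eqn{K_1^2}).
#' @param M_malignant sup bound on \eqn{|x_2|^2} (default \eqn{K_2^2}).
#' @return Named numeric \code{c(k1 = ..., k2 = ...)}.
#' @export
growth_constants <- function(params, M_healthy = params$K1^2,
                             M_malignant = params$K2^2) {
  stopifnot(inherits(params, "tumor_params"))
  if (M_healthy < 0 || M_malignant < 0)
    stop("sup bounds must be non-negative", call. = FALSE)
  k1 <- 4 * (params$alpha1^2 +
             params$alpha1^2 / params$K1^2 * M_healthy +
             params$beta1^2 * M_malignant +
             params$epsilon^2 * params$gamma^2)
  k2 <- 4 * (params$alpha2^2 +
             params$alpha2^2 / params$K2^2 * M_malignant +
             params$beta2^2 * M_healthy +
             params$gamma^2)
  c(k1 = k1, k2 = k2)
}

#' Lipschitz constants of the right-hand sides
#'
#' With the non-varied component held at its sup (the convention of the
#' derivation, which bounds cross terms by sup values), the one-variable
#' Lipschitz bounds \eqn{|F_i(a) - F_i(b)|^2 \le \bar k_i |a_i - b_i|^2} hold
#' with
#' \deqn{\bar k_1 = 4\alpha_1^2 + \frac{4\alpha_1^2}{K_1^2}(2M_5 + 2M_6) +
#'   4\beta_1^2 M_7 + 4\varepsilon^2\gamma^2, \qquad
#'   \bar k_2 = 4\alpha_2^2 + \frac{4\alpha_2^2}{K_2^2}(2M_8 + 2M_9) +
#'   4\beta_2^2 M_{10} + 4\gamma^2.}
#' Sup slots collapse as in \code{\link{growth_constants}}.
#'
#' @inheritParams growth_constants
#' @return Named numeric \code{c(kbar1 = ..., kbar2 = ...)}.
#' @export
lipschitz_constants <- function(params, M_healthy = params$K1^2,
                                M_malignant = params$K2^2) {
  stopifnot(inherits(params, "tumor_params"))
  if (M_healthy < 0 || M_malignant < 0)
    stop("sup bounds must be non-negative", call. = FALSE)
  kbar1 <- 4 * params$alpha1^2 +
    4 * params$alpha1^2 / params$K1^2 * (2 * M_healthy + 2 * M_healthy) +
    4 * params$beta1^2 * M_malignant +
    4 * params$epsilon^2 * params$gamma^2
  kbar2 <- 4 * params$alpha2^2 +
    4 * params$alpha2^2 / params$K2^2 * (2 * M_malignant + 2 * M_malignant) +
    4 * params$beta2^2 * M_healthy +
    4 * params$gamma^2
  c(kbar1 = kbar1, kbar2 = kbar2)
}

#' Brute-force verification of the growth and Lipschitz inequalities
#'
#' Samples states uniformly in the box implied by the sup bounds
#' (\eqn{0 \le x_1 \le \sqrt{M_{healthy}}},
#' \eqn{0 \le x_2 \le \sqrt{M_{malignant}}}) and checks
#' \eqn{|F_i|^2 \le k_i(1 + |x_i|^2)} at every sample, and
#' \eqn{|F_i(a) - F_i(b)|^2 \le \bar k_i |a_i - b_i|^2} on sampled pairs with
#' the cross variable fixed at its sup (matching the derivation). Reports the
#' worst observed ratios; \code{growth_verified}/\code{lipschitz_verified} are
#' set only if no sample violates the bound. Constants can be overridden to
#' demonstrate failure detection.
#'
#' @inheritParams growth_constants
#' @param n_samples number of sampled states/pairs (>= 100).
#' @param seed integer seed for the sampler (recorded in the report).
#' @param k,kbar optional overrides of the constants (length-2 vectors), used
#'   to demonstrate that undersized constants are caught.
#' @return A list of class \code{"growth_lipschitz_report"}.
#' @export
verify_conditions <- function(params, M_healthy = params$K1^2,
                              M_malignant = params$K2^2,
                              n_samples = 10000L, seed = 1L,
                              k = NULL, kbar = NULL) {
  stopifnot(inherits(params, "tumor_params"))
  if (n_samples < 100L) stop("'n_samples' must be >= 100", call. = FALSE)
  if (is.null(k)) k <- growth_constants(params, M_healthy, M_malignant)
  if (is.null(kbar)) kbar <- lipschitz_constants(params, M_healthy, M_malignant)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  s1 <- sqrt(M_healthy); s2 <- sqrt(M_malignant)
  # six uniforms per sample, drawn sample-by-sample so that runs at the same
  # seed nest: the worst observed ratio is then non-decreasing in n_samples
  u <- matrix(stats::runif(6L * n_samples), nrow = 6L)
  x1 <- u[1, ] * s1
  x2 <- u[2, ] * s2

  F1 <- params$alpha1 * x1 * (1 - x1 / params$K1) -
        params$beta1 * x1 * x2 - params$epsilon * params$gamma * x1
  F2 <- params$alpha2 * x2 * (1 - x2 / params$K2) -
        params$beta2 * x1 * x2 - params$gamma * x2
  g1 <- F1^2 / (k[[1]] * (1 + x1^2))
  g2 <- F2^2 / (k[[2]] * (1 + x2^2))

  # Lipschitz in the own variable, cross variable pinned at its sup
  a1 <- u[3, ] * s1; b1 <- u[4, ] * s1
  a2 <- u[5, ] * s2; b2 <- u[6, ] * s2
  f1 <- function(x1, x2) params$alpha1 * x1 * (1 - x1 / params$K1) -
    params$beta1 * x1 * x2 - params$epsilon * params$gamma * x1
  f2 <- function(x1, x2) params$alpha2 * x2 * (1 - x2 / params$K2) -
    params$beta2 * x1 * x2 - params$gamma * x2
  d1 <- (f1(a1, s2) - f1(b1, s2))^2
  d2 <- (f2(s1, a2) - f2(s1, b2))^2
  keep1 <- abs(a1 - b1) > 0; keep2 <- abs(a2 - b2) > 0
  l1 <- d1[keep1] / (kbar[[1]] * (a1 - b1)[keep1]^2)
  l2 <- d2[keep2] / (kbar[[2]] * (a2 - b2)[keep2]^2)

  worst <- c(growth1 = max(g1), growth2 = max(g2),
             lipschitz1 = max(l1), lipschitz2 = max(l2))
  viol_idx <- if (max(l1) > 1) which.max(d1 / (kbar[[1]] * (a1 - b1)^2)) else NA_integer_

  structure(list(
    k = k, kbar = kbar,
    M_bounds = c(M1 = M_healthy, M2 = M_malignant, M3 = M_malignant,
                 M4 = M_healthy, M5 = M_healthy, M6 = M_healthy,
                 M7 = M_malignant, M8 = M_malignant, M9 = M_malignant,
                 M10 = M_healthy),
    worst_ratio = worst,
    growth_verified = max(g1, g2) <= 1,
    lipschitz_verified = max(l1, l2) <= 1,
    violating_pair = if (!is.na(viol_idx))
      c(a = a1[viol_idx], b = b1[viol_idx]) else NULL,
    n_samples = n_samples, seed = seed
  ), class = "growth_lipschitz_report")
}

#' @export
print.growth_lipschitz_report <- function(x, ...) {
  cat("existence/uniqueness constants and brute-force verification\n")
  cat(sprintf("  k1 = %.6g, k2 = %.6g; kbar1 = %.6g, kbar2 = %.6g\n",
              x$k[[1]], x$k[[2]], x$kbar[[1]], x$kbar[[2]]))
  cat(sprintf("  worst ratios: growth (%.4g, %.4g), Lipschitz (%.4g, %.4g)\n",
              x$worst_ratio["growth1"], x$worst_ratio["growth2"],
              x$worst_ratio["lipschitz1"], x$worst_ratio["lipschitz2"]))
  cat(sprintf("  growth verified: %s; Lipschitz verified: %s (n = %d, seed = %d)\n",
              x$growth_verified, x$lipschitz_verified, x$n_samples, x$seed))
  invisible(x)
}

## Save/restore of the global RNG state so seeded internals do not perturb the
## caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
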