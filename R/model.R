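#' Parameters of the competition/radiation model
#'
#' The two-population system couples logistic growth of healthy (\eqn{x_1})
#' and malignant (\eqn{x_2}) cell proportions with Lotka-Volterra competition
#' and a continuous radiation dose:
#' \deqn{F_1 = \alpha_1 x_1 (1 - x_1/K_1) - \beta_1 x_1 x_2 -
#'   \varepsilon\gamma x_1,}
#' \deqn{F_2 = \alpha_2 x_2 (1 - x_2/K_2) - \beta_2 x_1 x_2 - \gamma x_2.}
#' \code{gamma} is the dose rate (Gray/hour) applied to the malignant
#' population; \code{epsilon} is the collateral fraction, so
#' \eqn{\varepsilon\gamma} is the kill rate inflicted on healthy cells.
#' \code{gamma = 0} encodes the untreated system.
#'
#' @param alpha1,alpha2 growth rates (per hour), > 0.
#' @param K1,K2 carrying capacities (proportion scale), > 0.
#' @param beta1 competition coefficient of malignant on healthy (per hour).
#' @param beta2 competition coefficient of healthy on malignant (per hour).
#' @param epsilon collateral-radiation fraction, >= 0 (dimensionless).
#' @param gamma radiation dose rate (Gray/hour), >= 0.
#' @return An object of class \code{"tumor_params"}.
#' @examples
#' p <- tumor_params(alpha1 = 9.7041e-4, alpha2 = 0.3396,
#'                   K1 = 1, K2 = 1, beta1 = 0.0433, beta2 = 0.2385,
#'                   epsilon = 0.0008, gamma = 0.75)
#' @export
tumor_params <- function(alpha1, alpha2, K1, K2, beta1, beta2,
                         epsilon = 0, gamma = 0) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, K1 = K1, K2 = K2,
            beta1 = beta1, beta2 = beta2, epsilon = epsilon, gamma = gamma)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative finite value", nm),
           call. = FALSE)
    p[[nm]] <- as.numeric(v)
  }
  if (p$alpha1 <= 0 || p$alpha2 <= 0)
    stop("growth rates 'alpha1' and 'alpha2' must be strictly positive",
         call. = FALSE)
  if (p$K1 <= 0 || p$K2 <= 0)
    stop("carrying capacities 'K1' and 'K2' must be strictly positive",
         call. = FALSE)
  structure(p, class = "tumor_params")
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("tumor-radiotherapy model parameters\n")
  cat(sprintf("  growth:      alpha1 = %g, alpha2 = %g (1/h)\n", x$alpha1, x$alpha2))
  cat(sprintf("  capacity:    K1 = %g, K2 = %g\n", x$K1, x$K2))
  cat(sprintf("  competition: beta1 = %g, beta2 = %g (1/h)\n", x$beta1, x$beta2))
  cat(sprintf("  radiation:   gamma = %g Gy/h, epsilon = %g%s\n",
              x$gamma, x$epsilon, if (x$gamma == 0) " (untreated)" else ""))
  invisible(x)
}

as_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 2L || any(!is.finite(state)))
    stop("'state' must be two finite values (x1, x2)", call. = FALSE)
  state
}

#' Model right-hand sides
#'
#' Evaluates the rates \eqn{(F_1, F_2)} at a state \eqn{(x_1, x_2)}.
#'
#' @param state numeric vector \code{c(x1, x2)}.
#' @param params a \code{\link{tumor_params}} object.
#' @return Named numeric vector \code{c(F1 = ..., F2 = ...)}.
#' @examples
#' p <- tumor_params(9.7041e-4, 0.3396, 1, 1, 0.0433, 0.2385, 0.0008, 0.75)
#' tumor_rhs(c(0.284, 0.284), p)
#' @export
tumor_rhs <- function(state, params) {
  stopifnot(inherits(params, "tumor_params"))
  s <- as_state(state)
  x1 <- s[1]; x2 <- s[2]
  c(F1 = params$alpha1 * x1 * (1 - x1 / params$K1) -
        params$beta1 * x1 * x2 - params$epsilon * params$gamma * x1,
    F2 = params$alpha2 * x2 * (1 - x2 / params$K2) -
        params$beta2 * x1 * x2 - params$gamma * x2)
}

#' Boundary equilibria of the model
#'
#' The cancer-free equilibrium \eqn{E_0 = (K_1(\alpha_1 -
#' \gamma\varepsilon)/\alpha_1,\, 0)} and the healthy-free equilibrium
#' \eqn{E_* = (0,\, K_2(\alpha_2 - \gamma)/\alpha_2)}. A coordinate that
#' comes out negative is reported as-is but flagged biologically infeasible.
#'
#' Note on \eqn{E_*}: the structurally consistent coefficient is the malignant
#' carrying capacity \eqn{K_2}; \code{E_star_printed} gives the variant with
#' \eqn{K_1} in its place for comparison (the two coincide when
#' \eqn{K_1 = K_2}).
#'
#' @param params a \code{\link{tumor_params}} object.
#' @return A list of class \code{"equilibrium_report"} with components
#'   \code{E0}, \code{E_star}, \code{E0_feasible}, \code{E_star_feasible},
#'   \code{E_star_printed}.
#' @export
equilibria <- function(params) {
  stopifnot(inherits(params, "tumor_params"))
  E0 <- c(x1 = params$K1 * (params$alpha1 - params$gamma * params$epsilon) /
            params$alpha1,
          x2 = 0)
  E_star <- c(x1 = 0,
              x2 = params$K2 * (params$alpha2 - params$gamma) / params$alpha2)
  E_star_printed <- c(x1 = 0,
                      x2 = params$K1 * (params$alpha2 - params$gamma) / params$alpha2)
  structure(list(
    E0 = E0, E_star = E_star, E_star_printed = E_star_printed,
    E0_feasible = all(E0 >= 0), E_star_feasible = all(E_star >= 0)
  ), class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("equilibria of the competition/radiation model\n")
  cat(sprintf("  E0     (cancer-free):  (%.6f, %g)%s\n", x$E0[1], x$E0[2],
              if (x$E0_feasible) "" else "  [infeasible]"))
  cat(sprintf("  E_star (healthy-free): (%g, %.6f)%s\n", x$E_star[1], x$E_star[2],
              if (x$E_star_feasible) "" else "  [infeasible]"))
  invisible(x)
}

#' Threshold ratios of the treated system
#'
#' The basic reproduction ratio of malignant cells
#' \eqn{R_0 = \alpha_2 / (\gamma + \beta_2 K_1)} (eradication is predicted
#' for \eqn{R_0 < 1}) and the net growth ratio of healthy cells
#' \eqn{R_h = (\alpha_1 - \varepsilon\gamma) / (\beta_1 K_2)}.
#'
#' @param params a \code{\link{tumor_params}} object.
#' @return Named numeric vector \code{c(R0 = ..., Rh = ...)}.
#' @export
thresholds <- function(params) {
  stopifnot(inherits(params, "tumor_params"))
  d0 <- params$gamma + params$beta2 * params$K1
  dh <- params$beta1 * params$K2
  if (d0 <= 0 || dh <= 0)
    stop("degenerate parameters: zero denominator in R0 or Rh", call. = FALSE)
  c(R0 = params$alpha2 / d0,
    Rh = (params$alpha1 - params$epsilon * params$gamma) / dh)
}

#' Analytic Jacobian of the model
#'
#' Partial derivatives of \eqn{(F_1, F_2)} with respect to \eqn{(x_1, x_2)},
#' evaluated analytically.
#'
#' @inheritParams tumor_rhs
#' @return A 2x2 numeric matrix.
#' @export
tumor_jacobian <- function(state, params) {
  stopifnot(inherits(params, "tumor_params"))
  s <- as_state(state)
  x1 <- s[1]; x2 <- s[2]
  matrix(c(
    params$alpha1 * (1 - 2 * x1 / params$K1) - params$beta1 * x2 -
      params$epsilon * params$gamma,
    -params$beta2 * x2,
    -params$beta1 * x1,
    params$alpha2 * (1 - 2 * x2 / params$K2) - params$beta2 * x1 - params$gamma
  ), nrow = 2, ncol = 2,
  dimnames = list(c("F1", "F2"), c("x1", "x2")))
}

#' As-printed Jacobian and eigenvalues at the cancer-free equilibrium
#'
#' The published form of \eqn{J(E_0)} differs from the analytic Jacobian of
#' the right-hand sides: its (2,2) entry reads
#' \eqn{-\beta_1 K_1(\alpha_1 - \gamma\varepsilon)/\alpha_1 - \gamma}
#' (no \eqn{\alpha_2} term, and \eqn{\beta_1} where the analytic form has
#' \eqn{\beta_2}). The analytic Jacobian is authoritative for all stability
#' verdicts in this package; this accessor exposes the printed variant for
#' side-by-side comparison.
#'
#' @param params a \code{\link{tumor_params}} object.
#' @return List with \code{jacobian} (2x2) and \code{eigenvalues} (length 2,
#'   \eqn{\lambda_1 = \gamma\varepsilon - \alpha_1} and the printed
#'   \eqn{\lambda_2}).
#' @export
jacobian_E0_printed <- function(params) {
  stopifnot(inherits(params, "tumor_params"))
  net <- params$alpha1 - params$gamma * params$epsilon
  l1 <- params$gamma * params$epsilon - params$alpha1
  l2 <- -params$gamma - params$beta1 * params$K1 * net / params$alpha1
  offdiag <- -params$beta1 * params$K1 * net / params$alpha1
  list(jacobian = matrix(c(l1, 0, offdiag, l2), 2, 2),
       eigenvalues = c(lambda1 = l1, lambda2 = l2))
}

matignon_ok <- function(lambda, mu) {
  all(abs(Arg(as.complex(lambda))) > mu * pi / 2)
}

#' Local stability of the boundary equilibria
#'
#' Computes the eigenvalues of the analytic Jacobian at each equilibrium and
#' applies the Matignon condition \eqn{|\arg\lambda| > \mu\pi/2} for the
#' requested fractional order. The simpler criterion
#' \eqn{\gamma\varepsilon < \alpha_1} (local stability of \eqn{E_0}) is
#' reported separately. Stability is computed for both equilibria even if one
#' is flagged infeasible.
#'
#' @param params a \code{\link{tumor_params}} object.
#' @param mu fractional order in (0, 1].
#' @return A list of class \code{"stability_report"}.
#' @export
local_stability <- function(params, mu) {
  stopifnot(inherits(params, "tumor_params"))
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0 || mu > 1)
    stop("'mu' must be a single value in (0, 1]", call. = FALSE)
  eq <- equilibria(params)
  ev0 <- eigen(tumor_jacobian(eq$E0, params), only.values = TRUE)$values
  evs <- eigen(tumor_jacobian(eq$E_star, params), only.values = TRUE)$values
  structure(list(
    mu = mu,
    equilibria = eq,
    eigenvalues_at_E0 = ev0,
    eigenvalues_at_E_star = evs,
    matignon_E0 = matignon_ok(ev0, mu),
    matignon_E_star = matignon_ok(evs, mu),
    dose_criterion = params$gamma * params$epsilon < params$alpha1,
    thresholds = thresholds(params),
    printed_E0 = jacobian_E0_printed(params)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("local stability at fractional order mu = %g\n", x$mu))
  print(x$equilibria)
  cat(sprintf("  eigenvalues at E0:     %s\n",
              paste(format(x$eigenvalues_at_E0, digits = 6), collapse = ", ")))
  cat(sprintf("  eigenvalues at E_star: %s\n",
              paste(format(x$eigenvalues_at_E_star, digits = 6), collapse = ", ")))
  cat(sprintf("  Matignon |arg| > mu*pi/2: E0 %s, E_star %s\n",
              x$matignon_E0, x$matignon_E_star))
  cat(sprintf("  gamma*epsilon < alpha1:   %s\n", x$dose_criterion))
  cat(sprintf("  R0 = %.6f, Rh = %.6f\n", x$thresholds["R0"], x$thresholds["Rh"]))
  invisible(x)
}

#' Check a trajectory against the invariant region
#'
#' The box \eqn{\Delta = \{0 \le x_1 \le K_1,\ 0 \le x_2 \le K_2\}} is
#' positively invariant for the model. This reports per-component ranges, the
#' fraction of points inside \eqn{\Delta} (with tolerance), and whether the
#' lim-sup bounds \eqn{x_i \le K_i} hold over the final quartile of the
#' trajectory.
#'
#' @param traj an \code{"ff_trajectory"} (see \code{\link{integrate_ffm}}),
#'   or any list with \code{times}, \code{x1}, \code{x2}.
#' @param params a \code{\link{tumor_params}} object.
#' @param tol tolerance band for boundary violations.
#' @return A list of class \code{"invariant_region_report"}.
#' @export
check_invariant_region <- function(traj, params, tol = 1e-9) {
  stopifnot(inherits(params, "tumor_params"))
  x1 <- traj$x1; x2 <- traj$x2
  if (length(x1) == 0L) stop("empty trajectory", call. = FALSE)
  inside <- x1 >= -tol & x1 <= params$K1 + tol &
            x2 >= -tol & x2 <= params$K2 + tol
  n <- length(x1)
  tail_idx <- seq.int(max(1L, n - n %/% 4L + 1L), n)
  structure(list(
    range_x1 = range(x1), range_x2 = range(x2),
    fraction_inside = mean(inside),
    all_inside = all(inside),
    limsup_ok = max(x1[tail_idx]) <= params$K1 + tol &&
                max(x2[tail_idx]) <= params$K2 + tol,
    tol = tol
  ), class = "invariant_region_report")
}

#' @export
print.invariant_region_report <- function(x, ...) {
  cat("invariant-region check (0 <= x1 <= K1, 0 <= x2 <= K2)\n")
  cat(sprintf("  x1 in [%.6g, %.6g]; x2 in [%.6g, %.6g]\n",
              x$range_x1[1], x$range_x1[2], x$range_x2[1], x$range_x2[2]))
  cat(sprintf("  fraction inside: %.4f; final-quartile lim-sup bounds: %s\n",
              x$fraction_inside, x$limsup_ok))
  invisible(x)
}
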