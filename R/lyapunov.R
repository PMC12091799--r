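#' Volterra-type Lyapunov function
#'
#' \deqn{L(x) = \sum_i \left(x_i - x_i^* - x_i^* \ln\frac{x_i}{x_i^*}\right)}
#' measured against a reference equilibrium \eqn{x^*}. For a reference
#' component equal to zero the logarithmic term is dropped (its limit as
#' \eqn{x^* \to 0}), leaving the bare \eqn{x_i} term; this keeps \eqn{L}
#' finite against both boundary equilibria. \eqn{L \ge 0} with equality only
#' at the reference point (restricted to states with \eqn{x_i > 0} wherever
#' \eqn{x_i^* > 0}).
#'
#' @param state numeric \code{c(x1, x2)}; components paired with a positive
#'   reference component must be strictly positive.
#' @param eq reference equilibrium \code{c(x1*, x2*)}.
#' @return Scalar, >= 0.
#' @examples
#' lyapunov_value(c(0.284, 0.284), c(0.381704, 0))
#' @export
lyapunov_value <- function(state, eq) {
  s <- as_state(state); e <- as_state(eq)
  total <- 0
  for (i in 1:2) {
    if (e[i] > 0) {
      if (s[i] <= 0)
        stop(sprintf("state component %d must be > 0 (reference component is %g)",
                     i, e[i]), call. = FALSE)
      total <- total + s[i] - e[i] - e[i] * log(s[i] / e[i])
    } else {
      total <- total + s[i]
    }
  }
  total
}

## Guard for the decomposition/second-derivative terms, which divide by the
## state components.
check_positive_state <- function(s, floor = 1e-12) {
  if (any(s < floor))
    stop(sprintf("state components below %g: Lyapunov decomposition undefined near extinction (use the burn-in handling of global_stability_check)",
                 floor), call. = FALSE)
}

#' Split of the Lyapunov derivative into competing non-negative parts
#'
#' Returns the two non-negative term groups \eqn{\Upsilon_1} (destabilizing)
#' and \eqn{\Upsilon_2} (stabilizing) of the published decomposition:
#' \deqn{\Upsilon_1 = \frac{(x_1-x_1^*)^2\alpha_1}{x_1} +
#'   \frac{(x_1-x_1^*)^2 x_2^*\beta_1}{x_1} +
#'   \frac{(x_2-x_2^*)^2\alpha_2}{x_2} +
#'   \frac{(x_2-x_2^*)^2 x_1^*\beta_2}{x_2},}
#' \deqn{\Upsilon_2 = \frac{(x_1-x_1^*)^2\alpha_1}{x_1 K_1} +
#'   \frac{(x_1-x_1^*)^2 x_2\beta_1}{x_1} +
#'   \frac{(x_1-x_1^*)^2\varepsilon\gamma}{x_1} +
#'   \frac{(x_2-x_2^*)^2\alpha_2}{x_2 K_2} +
#'   \frac{(x_2-x_2^*)^2 x_1\beta_2}{x_2} +
#'   \frac{(x_2-x_2^*)^2\gamma}{x_2}.}
#' Their difference equals the Volterra gradient applied to the right-hand
#' sides evaluated at the deviation from equilibrium,
#' \eqn{\sum_i (1 - x_i^*/x_i) F_i(x - x^*)} with the quadratic self-limitation
#' linearized, not the along-trajectory derivative \eqn{dL/dt} (see the
#' methods vignette); \eqn{\Upsilon_1 < \Upsilon_2} is the LaSalle-style
#' dominance condition used as the global-stability diagnostic.
#'
#' @param state numeric \code{c(x1, x2)}, strictly positive.
#' @param params a \code{\link{tumor_params}} object.
#' @param eq reference equilibrium \code{c(x1*, x2*)}.
#' @return Named numeric \code{c(upsilon1 = ..., upsilon2 = ...)}, both >= 0.
#' @export
lyapunov_decomposition <- function(state, params, eq) {
  stopifnot(inherits(params, "tumor_params"))
  s <- as_state(state); e <- as_state(eq)
  check_positive_state(s)
  d1 <- s[1] - e[1]; d2 <- s[2] - e[2]
  u1 <- d1^2 * params$alpha1 / s[1] +
        d1^2 * e[2] * params$beta1 / s[1] +
        d2^2 * params$alpha2 / s[2] +
        d2^2 * e[1] * params$beta2 / s[2]
  u2 <- d1^2 * params$alpha1 / (s[1] * params$K1) +
        d1^2 * s[2] * params$beta1 / s[1] +
        d1^2 * params$epsilon * params$gamma / s[1] +
        d2^2 * params$alpha2 / (s[2] * params$K2) +
        d2^2 * s[1] * params$beta2 / s[2] +
        d2^2 * params$gamma / s[2]
  c(upsilon1 = u1, upsilon2 = u2)
}

#' Along-trajectory derivative of the Lyapunov function
#'
#' The chain rule value \eqn{dL/dt = (1 - x_1^*/x_1)F_1 + (1 - x_2^*/x_2)F_2}
#' with the right-hand sides evaluated at the state. This is the quantity a
#' finite difference of \eqn{L} along a simulated trajectory reproduces, and
#' the one \code{\link{lyapunov_second_derivative}} differentiates.
#'
#' @inheritParams lyapunov_decomposition
#' @return Scalar.
#' @export
lyapunov_derivative <- function(state, params, eq) {
  stopifnot(inherits(params, "tumor_params"))
  s <- as_state(state); e <- as_state(eq)
  check_positive_state(s)
  f <- tumor_rhs(s, params)
  (1 - e[1] / s[1]) * f[[1]] + (1 - e[2] / s[2]) * f[[2]]
}

#' Second time derivative of the Lyapunov function
#'
#' Evaluates
#' \deqn{\frac{d\dot L}{dt} = \left(\frac{\dot x_1}{x_1}\right)^2 x_1^* +
#'   \left(\frac{\dot x_2}{x_2}\right)^2 x_2^* +
#'   \left(1-\frac{x_1^*}{x_1}\right)\ddot x_1 +
#'   \left(1-\frac{x_2^*}{x_2}\right)\ddot x_2}
#' with \eqn{\dot x} the analytic right-hand sides and \eqn{\ddot x} their
#' analytic time derivatives (product rule through the state):
#' \eqn{\ddot x_1 = \alpha_1\dot x_1(1 - x_1/K_1) - \alpha_1 x_1\dot x_1/K_1 -
#' \beta_1\dot x_1 x_2 - \beta_1 x_1\dot x_2 - \varepsilon\gamma\dot x_1}, and
#' symmetrically for \eqn{\ddot x_2}. Vanishes at a fixed point.
#'
#' @inheritParams lyapunov_decomposition
#' @return Scalar.
#' @export
lyapunov_second_derivative <- function(state, params, eq) {
  stopifnot(inherits(params, "tumor_params"))
  s <- as_state(state); e <- as_state(eq)
  check_positive_state(s)
  x1 <- s[1]; x2 <- s[2]
  f <- tumor_rhs(s, params)
  xd1 <- f[[1]]; xd2 <- f[[2]]
  xdd1 <- params$alpha1 * xd1 * (1 - x1 / params$K1) -
          params$alpha1 * x1 * xd1 / params$K1 -
          params$beta1 * xd1 * x2 - params$beta1 * x1 * xd2 -
          params$epsilon * params$gamma * xd1
  xdd2 <- params$alpha2 * xd2 * (1 - x2 / params$K2) -
          params$alpha2 * x2 * xd2 / params$K2 -
          params$beta2 * xd1 * x2 - params$beta2 * x1 * xd2 -
          params$gamma * xd2
  (xd1 / x1)^2 * e[1] + (xd2 / x2)^2 * e[2] +
    (1 - e[1] / x1) * xdd1 + (1 - e[2] / x2) * xdd2
}

#' Lyapunov trace and global-stability verdict along a trajectory
#'
#' Samples \eqn{L}, the \eqn{\Upsilon_1/\Upsilon_2} decomposition, the
#' chain-rule derivative \eqn{dL/dt} and the second derivative along a
#' computed trajectory, then summarizes: the fraction of evaluable points with
#' \eqn{\Upsilon_1 < \Upsilon_2}, the fraction of steps on which \eqn{L} does
#' not increase, and the initial/final \eqn{L}. Points with a state component
#' below \code{floor} (extinction tail) are excluded from the
#' division-by-state columns and counted in \code{n_excluded}. The closing
#' sufficient condition \eqn{R_0 < 1,\ R_h > 1} is reported as a boolean
#' alongside the numeric evidence and never used to short-circuit it.
#'
#' @param traj an \code{"ff_trajectory"} (or list with \code{times},
#'   \code{x1}, \code{x2}).
#' @param params a \code{\link{tumor_params}} object.
#' @param eq reference equilibrium \code{c(x1*, x2*)}.
#' @param floor positivity floor below which decomposition columns are
#'   excluded (default \code{1e-9}).
#' @return A list of class \code{"lyapunov_report"}: \code{trace} (data frame
#'   of class \code{"lyapunov_trace"} with columns \code{time}, \code{L},
#'   \code{upsilon1}, \code{upsilon2}, \code{dLdt}, \code{d2Ldt2}) and summary
#'   fields.
#' @export
global_stability_check <- function(traj, params, eq, floor = 1e-9) {
  stopifnot(inherits(params, "tumor_params"))
  e <- as_state(eq)
  n <- length(traj$times)
  if (n == 0L) stop("empty trajectory", call. = FALSE)
  L <- u1 <- u2 <- dL <- d2L <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    s <- c(traj$x1[k], traj$x2[k])
    ok_L <- all(s[e > 0] > 0) && all(s >= 0)
    if (ok_L) L[k] <- lyapunov_value(s, e)
    if (all(s >= floor)) {
      d <- lyapunov_decomposition(s, params, e)
      u1[k] <- d[1]; u2[k] <- d[2]
      dL[k] <- lyapunov_derivative(s, params, e)
      d2L[k] <- lyapunov_second_derivative(s, params, e)
    }
  }
  trace <- structure(
    data.frame(time = traj$times, L = L, upsilon1 = u1, upsilon2 = u2,
               dLdt = dL, d2Ldt2 = d2L),
    class = c("lyapunov_trace", "data.frame"))
  evaluable <- !is.na(u1)
  dL_steps <- diff(L[!is.na(L)])
  th <- thresholds(params)
  structure(list(
    trace = trace,
    eq = e,
    n_excluded = sum(!evaluable),
    fraction_upsilon1_lt_upsilon2 = if (any(evaluable))
      mean(u1[evaluable] < u2[evaluable]) else NA_real_,
    monotone_decrease_fraction = if (length(dL_steps))
      mean(dL_steps <= 1e-10) else NA_real_,
    L_initial = L[1], L_final = L[n],
    sufficient_condition = unname(th["R0"] < 1 && th["Rh"] > 1),
    thresholds = th
  ), class = "lyapunov_report")
}

#' @export
print.lyapunov_report <- function(x, ...) {
  cat("Lyapunov global-stability diagnostics\n")
  cat(sprintf("  reference equilibrium: (%.6g, %.6g)\n", x$eq[1], x$eq[2]))
  cat(sprintf("  L: initial %.6g -> final %.6g\n", x$L_initial, x$L_final))
  cat(sprintf("  upsilon1 < upsilon2 at %.1f%% of evaluable points (%d excluded below floor)\n",
              100 * x$fraction_upsilon1_lt_upsilon2, x$n_excluded))
  cat(sprintf("  L non-increasing on %.1f%% of steps\n",
              100 * x$monotone_decrease_fraction))
  cat(sprintf("  sufficient condition R0 < 1 and Rh > 1: %s (R0 = %.4f, Rh = %.4f)\n",
              x$sufficient_condition, x$thresholds["R0"], x$thresholds["Rh"]))
  invisible(x)
}
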