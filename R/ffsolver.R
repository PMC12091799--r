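#' Uniform simulation grid
#'
#' @param dt step size (hours), > 0.
#' @param t_end horizon (hours); \code{n_steps} is derived as
#'   \code{ceiling(t_end / dt)} so the grid covers the horizon.
#' @param n_steps alternative to \code{t_end}: explicit step count (>= 1).
#' @param t0 start time; the stepping scheme assumes 0.
#' @return Object of class \code{"simulation_grid"} with \code{t0}, \code{dt},
#'   \code{n_steps} and the node vector \code{times}.
#' @export
simulation_grid <- function(dt, t_end = NULL, n_steps = NULL, t0 = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive value", call. = FALSE)
  if (t0 != 0) stop("the stepping scheme starts at t0 = 0", call. = FALSE)
  if (is.null(n_steps)) {
    if (is.null(t_end) || t_end <= 0)
      stop("supply 't_end' > 0 or 'n_steps'", call. = FALSE)
    n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  structure(list(t0 = 0, dt = dt, n_steps = n_steps,
                 times = dt * (0:n_steps)),
            class = "simulation_grid")
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf("uniform grid: dt = %g h, %d steps, horizon %g h\n",
              x$dt, x$n_steps, x$dt * x$n_steps))
  invisible(x)
}

#' Two-step Lagrange scheme weights
#'
#' The pair of weights multiplying the newer and older history node in the
#' fractal-fractional two-step (Adams-Bashforth-type) scheme, for step index
#' \code{r} and history index \code{v}: with lag indices \eqn{q = r + 1 - v}
#' and \eqn{p = r - v},
#' \deqn{w_1 = q^\mu(q + 1 + \mu) - p^\mu(1 + 2\mu + q), \qquad
#'       w_2 = q^{\mu+1} - p^\mu(q + \mu).}
#' At \eqn{\mu = 1} these collapse to \eqn{(3, 1)} for every lag, recovering
#' the classical two-step Adams-Bashforth rule (with the \eqn{\Gamma(\mu+2)}
#' prefactor supplying the 1/2).
#'
#' @param r step index (>= 0).
#' @param v history index, \code{0 <= v <= r}; may be a vector.
#' @param mu fractional order in (0, 1].
#' @return Data frame with columns \code{q}, \code{p}, \code{w1}, \code{w2}.
#' @examples
#' scheme_weights(5, 5, 0.8)   # newest node: w1 = 2 + mu, w2 = 1
#' scheme_weights(1, 0, 0.5)
#' @export
scheme_weights <- function(r, v, mu) {
  if (any(v > r) || any(v < 0)) stop("need 0 <= v <= r", call. = FALSE)
  if (mu <= 0 || mu > 1) stop("'mu' must be in (0, 1]", call. = FALSE)
  q <- r + 1 - v
  p <- r - v
  data.frame(q = q, p = p,
             w1 = q^mu * (q + 1 + mu) - p^mu * (1 + 2 * mu + q),
             w2 = q^(mu + 1) - p^mu * (q + mu))
}

new_trajectory <- function(times, x1, x2, meta) {
  structure(list(times = times, x1 = x1, x2 = x2, meta = meta),
            class = "ff_trajectory")
}

#' @export
print.ff_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("trajectory (%s): %d points on [0, %g] h\n",
              x$meta$scheme, n, x$times[n]))
  cat(sprintf("  x1: %.6g -> %.6g;  x2: %.6g -> %.6g\n",
              x$x1[1], x$x1[n], x$x2[1], x$x2[n]))
  if (!is.null(x$meta$spec))
    cat(sprintf("  mu = %g, nu = %g, dt = %g\n",
                x$meta$spec$mu, x$meta$spec$nu, x$meta$grid$dt))
  invisible(x)
}

#' @export
plot.ff_trajectory <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$x1, x$x2), type = "l", lty = 1,
                    col = c("forestgreen", "firebrick"),
                    xlab = "time (h)", ylab = "cell proportion", ...)
  graphics::legend("topright", c("healthy x1", "malignant x2"),
                   col = c("forestgreen", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.ff_trajectory <- function(x, ...) {
  data.frame(t = x$times, x1 = x$x1, x2 = x$x2)
}

#' Fractal-fractional two-step Lagrange integrator
#'
#' Advances the competition/radiation system under the Mittag-Leffler-kernel
#' fractal-fractional derivative with the explicit two-step scheme
#' \deqn{x^{r+1} = x^0 + \frac{\nu t_r^{\nu-1}(1-\mu)}{AB(\mu)} A(t_r, x^r) +
#'   \frac{\mu\nu(\Delta t)^\mu}{AB(\mu)\Gamma(\mu+2)} \sum_{v=0}^{r}
#'   \left[t_v^{\nu-1} A(t_v, x^v)\, w_1 - t_{v-1}^{\nu-1} A(t_{v-1}, x^{v-1})
#'   \, w_2\right]}
#' with \eqn{A = (F_1, F_2)} the model right-hand sides and \eqn{(w_1, w_2)}
#' the lag-dependent weights of \code{\link{scheme_weights}}. Conventions:
#' the \code{v = 0} term uses \eqn{x^{-1} := x^0}, \eqn{t_{-1} := t_0}; for
#' \eqn{\nu < 1} the singular fractal weight at \eqn{t_0 = 0} is regularized
#' to \eqn{t := \Delta t} (exact when \eqn{\nu = 1}) and a message is logged.
#' Cost is O(n_steps^2) through the history sum; when \eqn{\mu = 1} the
#' weights are lag-independent, the sum telescopes, and an algebraically
#' identical O(n_steps) recurrence is used.
#'
#' Small negative values near extinction are reported raw; a warning is
#' issued if any component drops below \code{-1e-9}. A non-finite state
#' aborts with the offending step.
#'
#' @param params a \code{\link{tumor_params}} object.
#' @param spec a \code{\link{fractional_spec}}.
#' @param grid a \code{\link{simulation_grid}}.
#' @param init non-negative initial state \code{c(x1, x2)}.
#' @param label optional scenario label stored in the metadata.
#' @return An \code{"ff_trajectory"}: \code{times}, \code{x1}, \code{x2} and
#'   \code{meta} (parameters, spec, grid, scheme identifier).
#' @examples
#' p <- tumor_params(9.7041e-4, 0.3396, 1, 1, 0.0433, 0.2385, 0.0008, 0.75)
#' tr <- integrate_ffm(p, fractional_spec(1, 1), simulation_grid(0.05, 10),
#'                     c(0.284, 0.284))
#' @export
integrate_ffm <- function(params, spec, grid, init, label = NULL) {
  stopifnot(inherits(params, "tumor_params"), inherits(spec, "ff_spec"),
            inherits(grid, "simulation_grid"))
  init <- as_state(init)
  if (any(init < 0)) stop("'init' must be non-negative", call. = FALSE)

  mu <- spec$mu; nu <- spec$nu
  dt <- grid$dt; N <- grid$n_steps
  times <- grid$times
  ab <- ab_normalization(mu)

  if (nu < 1)
    message(sprintf(
      "nu = %g < 1: fractal weight at t = 0 regularized to one cell (t := dt)", nu))

  # fractal node weights t_v^(nu-1), v = 0..N, with one-cell regularization
  g <- times^(nu - 1)
  g[1] <- dt^(nu - 1)
  # t_r^(nu-1) used by the local term (same regularization at r = 0)
  gloc <- g

  x <- matrix(NA_real_, nrow = 2, ncol = N + 1L)
  x[, 1] <- init
  A <- matrix(NA_real_, nrow = 2, ncol = N + 1L)   # rhs at nodes
  A[, 1] <- tumor_rhs(init, params)

  Csum <- mu * nu * dt^mu / (ab * gamma(mu + 2))
  Cloc <- nu * (1 - mu) / ab

  if (mu == 1) {
    # weights are (3, 1) for every lag: the history sum telescopes and the
    # scheme is the cumulative two-step Adams-Bashforth (Cloc = 0)
    for (r in 0:(N - 1L)) {
      gA_r  <- g[r + 1L] * A[, r + 1L]
      gA_rm <- if (r == 0L) g[1L] * A[, 1L] else g[r] * A[, r]
      x[, r + 2L] <- x[, r + 1L] + Csum * (3 * gA_r - gA_rm)
      check_step(x[, r + 2L], r + 1L)
      A[, r + 2L] <- tumor_rhs(x[, r + 2L], params)
    }
  } else {
    # lag-indexed weights, q = 1..N (p = q - 1)
    q <- as.numeric(1:N)
    p <- q - 1
    w1 <- q^mu * (q + 1 + mu) - p^mu * (1 + 2 * mu + q)
    w2 <- q^(mu + 1) - p^mu * (q + mu)
    GA <- matrix(NA_real_, nrow = 2, ncol = N + 1L)  # t_v^(nu-1) A_v
    GA[, 1] <- g[1] * A[, 1]
    for (r in 0:(N - 1L)) {
      idx <- 1:(r + 1L)              # v = 0..r stored at columns v + 1
      wq1 <- w1[(r + 1L):1]          # w1[q], q = r + 1 - v
      wq2 <- w2[(r + 1L):1]
      # older-node factors: v - 1, with the v = 0 convention (:= node 0)
      prev <- c(1L, idx[-length(idx)])
      s1 <- GA[, idx, drop = FALSE] %*% wq1
      s2 <- GA[, prev, drop = FALSE] %*% wq2
      x[, r + 2L] <- init + Cloc * gloc[r + 1L] * A[, r + 1L] +
        Csum * (s1 - s2)
      check_step(x[, r + 2L], r + 1L)
      A[, r + 2L] <- tumor_rhs(x[, r + 2L], params)
      GA[, r + 2L] <- g[r + 2L] * A[, r + 2L]
    }
  }

  if (min(x) < -1e-9)
    warning(sprintf("trajectory dips below -1e-9 (min = %g); values reported raw",
                    min(x)), call. = FALSE)

  new_trajectory(times, x[1, ], x[2, ],
                 meta = list(params = params, spec = spec, grid = grid,
                             scheme = "ffm-lagrange2", label = label,
                             converged = NA))
}

check_step <- function(xnew, step) {
  if (any(!is.finite(xnew)))
    stop(sprintf("integration blew up at step %d (non-finite state)", step),
         call. = FALSE)
}

#' Classical adaptive reference integrator
#'
#' Solves the classical (\eqn{\mu = \nu = 1}) system with an adaptive
#' high-order method (\code{deSolve::ode}, lsoda, rel/abs tolerance 1e-10),
#' sampled onto the requested grid. Serves as the oracle for the classical
#' limit of the fractal-fractional scheme.
#'
#' @inheritParams integrate_ffm
#' @param rtol,atol solver tolerances.
#' @return An \code{"ff_trajectory"} with scheme \code{"classical-lsoda"}.
#' @export
integrate_classical <- function(params, grid, init, rtol = 1e-10, atol = 1e-10,
                                label = NULL) {
  stopifnot(inherits(params, "tumor_params"), inherits(grid, "simulation_grid"))
  init <- as_state(init)
  if (any(init < 0)) stop("'init' must be non-negative", call. = FALSE)
  deriv <- function(t, y, parms) list(unname(tumor_rhs(y, params)))
  sol <- deSolve::ode(y = c(x1 = init[1], x2 = init[2]), times = grid$times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("classical solver failed; see deSolve diagnostics", call. = FALSE)
  new_trajectory(sol[, "time"], sol[, "x1"], sol[, "x2"],
                 meta = list(params = params,
                             spec = fractional_spec(1, 1), grid = grid,
                             scheme = "classical-lsoda", label = label,
                             converged = TRUE))
}

#' Values of a trajectory at selected times
#'
#' Extracts (grid-matched, else linearly interpolated) values at the
#' requested times.
#'
#' @param traj an \code{"ff_trajectory"}.
#' @param times times within the trajectory range.
#' @return Data frame with columns \code{t}, \code{x1}, \code{x2}.
#' @export
sample_trajectory <- function(traj, times) {
  rng <- range(traj$times)
  if (any(times < rng[1] - 1e-12) || any(times > rng[2] + 1e-12))
    stop("requested times outside the trajectory range", call. = FALSE)
  data.frame(
    t = times,
    x1 = stats::approx(traj$times, traj$x1, xout = times)$y,
    x2 = stats::approx(traj$times, traj$x2, xout = times)$y)
}

#' Self-convergence study of the stepping scheme
#'
#' Integrates at each step size in \code{dt_list} (descending), measures the
#' max-norm difference between successive refinements on the common coarse
#' time grid, and reports empirical order estimates from Richardson ratios.
#'
#' @inheritParams integrate_ffm
#' @param t_end horizon (hours).
#' @param dt_list descending step sizes, at least 2 (each should divide
#'   \code{t_end}).
#' @return Data frame with columns \code{dt_coarse}, \code{dt_fine},
#'   \code{max_diff}, \code{order} (NA on the first row).
#' @export
convergence_study <- function(params, spec, init, t_end, dt_list) {
  if (length(dt_list) < 2L || any(diff(dt_list) >= 0))
    stop("'dt_list' must be descending with at least 2 entries", call. = FALSE)
  runs <- lapply(dt_list, function(dt)
    integrate_ffm(params, spec, simulation_grid(dt, t_end), init))
  probe <- seq(0, t_end, by = dt_list[1])
  vals <- lapply(runs, function(tr) sample_trajectory(tr, probe))
  md <- vapply(seq_len(length(runs) - 1L), function(i) {
    max(abs(vals[[i]]$x1 - vals[[i + 1]]$x1),
        abs(vals[[i]]$x2 - vals[[i + 1]]$x2))
  }, numeric(1))
  ord <- rep(NA_real_, length(md))
  for (i in seq_along(md)[-1]) {
    h_ratio <- dt_list[i] / dt_list[i + 1]
    if (md[i] > 0) ord[i] <- log(md[i - 1] / md[i]) / log(dt_list[i - 1] / dt_list[i])
  }
  data.frame(dt_coarse = dt_list[-length(dt_list)],
             dt_fine = dt_list[-1],
             max_diff = md, order = ord)
}

#' Round half away from zero
#'
#' Table-style rounding: 0.00005 rounds to 0.0001 rather than to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 4) {
  m <- 10^digits
  trunc(x * m + sign(x) * 0.5) / m
}

#' Write a trajectory to a commented CSV
#'
#' Emits provenance header comments (\code{# patient=}, \code{# mu=},
#' \code{# nu=}, \code{# dt=}, \code{# gamma=}, \code{# scheme=}) followed by
#' \code{t,x1,x2} rows at full double precision. Bit-stable for identical
#' inputs.
#'
#' @param traj an \code{"ff_trajectory"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- traj$meta
  writeLines(c(
    sprintf("# patient=%s", if (is.null(meta$label)) "NA" else meta$label),
    sprintf("# mu=%.17g", meta$spec$mu),
    sprintf("# nu=%.17g", meta$spec$nu),
    sprintf("# dt=%.17g", meta$grid$dt),
    sprintf("# gamma=%.17g", meta$params$gamma),
    sprintf("# scheme=%s", meta$scheme),
    "t,x1,x2"), con)
  writeLines(sprintf("%.17g,%.17g,%.17g", traj$times, traj$x1, traj$x2), con)
  invisible(path)
}
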