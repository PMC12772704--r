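#' Simulation configuration for the rate network
#'
#' Time is measured in units of the membrane time constant (the leak term in
#' `dx/dt = -x + W S(x)` has unit rate). The activation is `tanh`, the odd
#' sigmoid with `S'(0) = 1` used throughout.
#'
#' @param dt Integration step (classical 4th-order fixed-step scheme);
#'   must be < 0.2 for a comfortable stability margin.
#' @param t_transient Time discarded before measurements.
#' @param t_measure Measurement window for time averages.
#' @param t_max Maximum integration time for convergence runs.
#' @param convergence_tol Threshold on `||dx/dt|| / sqrt(N)` (per-neuron
#'   normalized, so the criterion is N-independent); convergence is declared
#'   after 5 consecutive checks spaced `check_interval` apart stay below it,
#'   and `t_fp` is the first crossing.
#' @param check_interval Spacing of convergence checks (time units).
#' @param x0_scale Per-coordinate standard deviation of the Gaussian initial
#'   condition.
#' @param t_renorm Renormalization interval of the Lyapunov tangent vector.
#' @param max_stored Cap on stored state samples per run (memory contract);
#'   the storage stride is chosen to respect it.
#' @return A `sim_config` object.
#' @export
sim_config <- function(dt = 0.05, t_transient = 100, t_measure = 1000,
                       t_max = 1000, convergence_tol = 1e-9,
                       check_interval = 1, x0_scale = 1, t_renorm = 1,
                       max_stored = 5000L) {
  stopifnot(dt > 0, dt < 0.2, t_transient >= 0, t_measure > 0, t_max > 0,
            convergence_tol > 0, check_interval > 0, x0_scale >= 0,
            t_renorm > 0, max_stored >= 2)
  structure(list(dt = dt, t_transient = t_transient, t_measure = t_measure,
                 t_max = t_max, convergence_tol = convergence_tol,
                 check_interval = check_interval, x0_scale = x0_scale,
                 t_renorm = t_renorm, max_stored = as.integer(max_stored)),
            class = "sim_config")
}

#' Draw a Gaussian initial condition
#'
#' @param N Dimension.
#' @param config A [sim_config()] (for `x0_scale`).
#' @param seed Seed; the draw is deterministic given it.
#' @return Numeric vector of length N.
#' @export
draw_x0 <- function(N, config = sim_config(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(mix_seed(seed, 202L))
  rnorm(N, sd = config$x0_scale)
}

#' Integrate the rate network
#'
#' Fixed-step 4th-order integration of `dx/dt = -x + W tanh(x)` up to
#' `config$t_max`, stopping early on convergence (see [sim_config()]).
#' States and derivatives are stored at a stride respecting
#' `config$max_stored`; the derivative norm `||dx/dt||` is recorded at every
#' step for path-length quadrature.
#'
#' @param W A `weight_matrix` or plain square matrix.
#' @param config A [sim_config()].
#' @param x0 Initial state (length-N vector).
#' @return An `rnn_trajectory`: list with `times`, `states` (T-by-N),
#'   `derivs`, `deriv_norms` (every step), `deriv_norm_dt`, `converged`,
#'   `t_fp`, `t_end`, `config`, and `W_params`.
#' @export
integrate_network <- function(W, config = sim_config(), x0) {
  M <- if (inherits(W, "weight_matrix")) W$values else W
  stopifnot(is.matrix(M), nrow(M) == ncol(M), length(x0) == nrow(M),
            all(is.finite(x0)), inherits(config, "sim_config"))
  n_steps <- round(config$t_max / config$dt)
  stride <- max(1L, ceiling(n_steps / (config$max_stored - 1L)))
  out <- rk4_integrate_cpp(M, as.numeric(x0), config$dt, config$t_max,
                           as.integer(stride), config$check_interval,
                           config$convergence_tol, 5L)
  out$t_fp <- if (out$converged) out$t_fp else NA_real_
  out$config <- config
  out$W_params <- if (inherits(W, "weight_matrix")) W$params else NULL
  class(out) <- "rnn_trajectory"
  out
}

#' @export
print.rnn_trajectory <- function(x, ...) {
  cat(sprintf("rnn_trajectory: N=%d, t_end=%.4g, %s\n",
              ncol(x$states), x$t_end,
              if (x$converged) sprintf("converged (t_fp=%.4g)", x$t_fp)
              else "not converged"))
  invisible(x)
}

#' Jacobian of the rate dynamics at a state
#'
#' `J_ij = -delta_ij + w_ij (1 - tanh^2(x_j))`. At `x = 0` this is `-I + W`;
#' in deeply saturated states the sensitivity factor vanishes and J
#' approaches `-I`.
#'
#' @param W A `weight_matrix` or plain matrix.
#' @param x State vector.
#' @return The N-by-N Jacobian matrix.
#' @export
jacobian_at <- function(W, x) {
  M <- if (inherits(W, "weight_matrix")) W$values else W
  stopifnot(is.matrix(M), length(x) == nrow(M), all(is.finite(x)))
  sp <- 1 - tanh(x)^2
  J <- M * rep(sp, each = nrow(M))
  diag(J) <- diag(J) - 1
  J
}

#' Maximal Lyapunov exponent (Benettin tangent-space method)
#'
#' Co-integrates one tangent vector under the linearized flow
#' `dv/dt = J(x(t)) v`, renormalizing every `config$t_renorm` and averaging
#' the accumulated log stretch over the measurement window (transient
#' discarded). Working in the tangent space avoids the nonlinear
#' contamination of finite trajectory separations.
#'
#' @param W A `weight_matrix` or plain matrix.
#' @param config A [sim_config()]; the run lasts
#'   `t_transient + t_measure`.
#' @param x0 Initial state; drawn via [draw_x0()] with `seed` if missing.
#' @param seed Seed for the initial state and tangent direction.
#' @return The exponent (units 1/time).
#' @export
lyapunov_max <- function(W, config = sim_config(), x0 = NULL, seed = 1L) {
  M <- if (inherits(W, "weight_matrix")) W$values else W
  stopifnot(is.matrix(M), nrow(M) == ncol(M), inherits(config, "sim_config"))
  N <- nrow(M)
  if (is.null(x0)) x0 <- draw_x0(N, config, seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(mix_seed(seed, 303L))
  v0 <- rnorm(N)
  benettin_cpp(M, as.numeric(x0), v0, config$dt, config$t_transient,
               config$t_measure, config$t_renorm)$lambda_max
}

# Stored samples inside the measurement window (t >= t_transient). A run
# that converged before the window opened sits at its fixed point, so the
# final sample represents the whole window.
.window_states <- function(traj) {
  stopifnot(inherits(traj, "rnn_trajectory"))
  keep <- traj$times >= traj$config$t_transient
  if (!any(keep)) {
    if (traj$converged) return(traj$states[nrow(traj$states), , drop = FALSE])
    stop("no stored samples inside the measurement window")
  }
  traj$states[keep, , drop = FALSE]
}

#' Participation-ratio dimensionality of a trajectory
#'
#' `PR = (sum mu_i)^2 / sum mu_i^2` over the eigenvalues `mu_i` of the
#' time covariance of the states in the measurement window (mean-subtracted
#' per neuron). PR = 1 for activity confined to one covariance mode and k
#' for k equal-variance modes; it lies in `[1, N]`.
#'
#' @param traj An `rnn_trajectory` from a fluctuating (non-convergent) run,
#'   or any run with `allow_converged = TRUE`.
#' @param allow_converged Override the fluctuating-regime precondition.
#' @return The participation ratio, or `NA` (degenerate) when the windowed
#'   activity has zero variance, as at a fixed point.
#' @export
participation_ratio <- function(traj, allow_converged = FALSE) {
  if (traj$converged && !allow_converged)
    stop("trajectory converged to a fixed point; PR is for fluctuating runs ",
         "(use allow_converged = TRUE to override)")
  X <- .window_states(traj)
  X <- sweep(X, 2L, colMeans(X))
  s2 <- svd(X, nu = 0, nv = 0)$d^2  # proportional to covariance eigenvalues
  tot <- sum(s2)
  if (tot <= 0) return(NA_real_)
  tot^2 / sum(s2^2)
}

#' Time-averaged activity statistics
#'
#' Per stored sample in the measurement window computes the population
#' activity standard deviation `sigma(t) = sqrt(mean(x^2))`, the mean-field
#' noise scale `sigma_n(t) = g * sqrt(mean(tanh(x)^2))` (the self-consistent
#' Gaussian drive of the mean-field picture), and the mean sensitivity
#' `mean(1 - tanh(x)^2)`, then time-averages each.
#'
#' @param traj An `rnn_trajectory`.
#' @param g Coupling gain; taken from the trajectory's weight params if
#'   missing.
#' @return List with `sigma`, `sigma_n`, `mean_sensitivity`.
#' @export
activity_stats <- function(traj, g = NULL) {
  if (is.null(g)) {
    if (is.null(traj$W_params)) stop("supply g (no ensemble params recorded)")
    g <- traj$W_params$g
  }
  X <- .window_states(traj)
  S <- tanh(X)
  list(sigma = mean(sqrt(rowMeans(X^2))),
       sigma_n = g * mean(sqrt(rowMeans(S^2))),
       mean_sensitivity = mean(1 - S^2))
}

#' Transient path length per neuron
#'
#' `L = N^{-1/2} integral_0^{t_fp} ||dx/dt|| dt` by trapezoidal quadrature
#' of the per-step derivative norms. Non-convergent runs are censored:
#' `L = NA` with `censored = TRUE`, never an error, so sweep summaries can
#' report censoring fractions.
#'
#' @param traj An `rnn_trajectory`.
#' @return List with `L`, `t_fp`, `censored`.
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "rnn_trajectory"))
  if (!traj$converged)
    return(list(L = NA_real_, t_fp = NA_real_, censored = TRUE))
  dt <- traj$deriv_norm_dt
  n_fp <- round(traj$t_fp / dt)
  dn <- traj$deriv_norms[seq_len(min(n_fp + 1L, length(traj$deriv_norms)))]
  N <- ncol(traj$states)
  L <- (sum(dn) - 0.5 * (dn[1] + dn[length(dn)])) * dt / sqrt(N)
  list(L = L, t_fp = traj$t_fp, censored = FALSE)
}

#' Newton search for fixed points
#'
#' Damped Newton iterations on `F(x) = -x + W tanh(x)` with the analytic
#' Jacobian, from `n_starts` Gaussian initial points (plus the origin, which
#' is always a fixed point). Converged roots are polished to
#' `||F||_inf < 1e-10`, deduplicated by Euclidean distance, and mirrored
#' through the odd symmetry `x* <-> -x*` of the dynamics. Each root's count
#' of unstable directions comes from the Jacobian eigenvalues.
#'
#' This is a census (a lower bound on the true count for N > 3), suitable
#' for modest N.
#'
#' @param W A `weight_matrix` or plain matrix.
#' @param n_starts Number of random starts.
#' @param start_radius Per-coordinate std of the Gaussian starts.
#' @param seed Seed for the starts.
#' @param dedupe_tol Euclidean deduplication tolerance.
#' @return List with `points` (list of vectors), `residuals`,
#'   `n_unstable_dims`, `n_distinct`, `n_failed_starts`.
#' @export
find_fixed_points <- function(W, n_starts = 100L, start_radius = 2,
                              seed = 1L, dedupe_tol = 1e-6) {
  M <- if (inherits(W, "weight_matrix")) W$values else W
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  N <- nrow(M)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(mix_seed(seed, 404L))
  roots <- list(rep(0, N))  # the origin, exactly
  n_failed <- 0L
  for (s in seq_len(n_starts)) {
    r <- .newton_root(M, rnorm(N, sd = start_radius))
    if (is.null(r)) { n_failed <- n_failed + 1L; next }
    roots[[length(roots) + 1L]] <- r
    roots[[length(roots) + 1L]] <- -r  # odd symmetry of tanh
  }
  P <- do.call(rbind, roots)
  kept <- P[1, , drop = FALSE]
  for (i in seq_len(nrow(P))[-1]) {
    d <- sqrt(colSums((t(kept) - P[i, ])^2))
    if (all(d > dedupe_tol)) kept <- rbind(kept, P[i, ])
  }
  points <- lapply(seq_len(nrow(kept)), function(i) kept[i, ])
  residuals <- vapply(points, function(p)
    max(abs(-p + drop(M %*% tanh(p)))), numeric(1))
  ok <- residuals < 1e-10
  points <- points[ok]; residuals <- residuals[ok]
  n_unstable <- vapply(points, function(p) {
    ev <- eigen(jacobian_at(M, p), only.values = TRUE)$values
    sum(Re(ev) > 0)
  }, integer(1))
  list(points = points, residuals = residuals,
       n_unstable_dims = n_unstable, n_distinct = length(points),
       n_failed_starts = n_failed)
}
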