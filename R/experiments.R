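#' Topological complexity across reciprocal correlations
#'
#' Evaluates the closed-form complexity on a tau grid at fixed effective
#' gain, the quantity behind the complexity-versus-symmetry curve: `c_raw`
#' decreases monotonically in tau, diverges as tau -> -1, and its positive
#' part `c_contribution = max(0, c)` is what survives in the exponential
#' fixed-point count.
#'
#' @param geff Effective gain.
#' @param tau_grid Grid of reciprocal correlations in `(-1, 1]` (a `-1`
#'   entry is flagged divergent, not an error... it cannot be combined with
#'   a `geff` parameterization and is therefore dropped with a warning).
#' @return Data.frame with columns `tau`, `geff`, `g`, `c_raw`, `c`,
#'   `c_contribution`, `below_onset`, `divergent`. Deterministic.
#' @export
complexity_curve <- function(geff = 1.05, tau_grid = seq(-0.95, 1, by = 0.05)) {
  if (any(tau_grid == -1)) {
    warning("tau = -1 dropped: g is undefined at fixed geff")
    tau_grid <- tau_grid[tau_grid != -1]
  }
  out <- complexity_closed_form(geff = geff, tau = tau_grid)
  out[, c("tau", "geff", "g", "c_raw", "c", "c_contribution",
          "below_onset", "divergent")]
}

#' Spectra and sample trajectories at fixed effective gain
#'
#' For each tau, samples one weight matrix, computes its full spectrum and a
#' short trajectory of a few sample neurons. With `geff > 1` every spectrum
#' has eigenvalues beyond `Re(lambda) = 1` (unstable origin); increasing tau
#' compresses the spectrum vertically, so unstable eigenvalues have smaller
#' imaginary parts and fluctuations slow.
#'
#' @param geff Effective gain.
#' @param tau_list Correlations to compare.
#' @param N Network size.
#' @param seed Root seed.
#' @param n_sample_neurons Number of trajectory components kept.
#' @param t_run Trajectory duration.
#' @return List with `spectra` (data.frame: re, im, N, g, tau, seed) and
#'   `trajectories` (data.frame: time, neuron, x, tau).
#' @export
spectra_experiment <- function(geff = 1.2, tau_list = c(-0.5, 0, 0.5),
                               N = 1000, seed = 1L, n_sample_neurons = 3L,
                               t_run = 100) {
  spectra <- list(); trajs <- list()
  for (tau in tau_list) {
    params <- ensemble_params(N = N, geff = geff, tau = tau, seed = seed)
    W <- sample_weights(params)
    ev <- weight_spectrum(W)$eigenvalues
    spectra[[length(spectra) + 1L]] <- data.frame(
      re = Re(ev), im = Im(ev), N = N, g = params$g, tau = tau, seed = seed)
    cfg <- sim_config(t_max = t_run, t_transient = 0, t_measure = t_run)
    traj <- integrate_network(W, cfg, draw_x0(N, cfg, seed))
    keep <- seq_len(min(n_sample_neurons, N))
    trajs[[length(trajs) + 1L]] <- data.frame(
      time = rep(traj$times, length(keep)),
      neuron = rep(keep, each = length(traj$times)),
      x = as.vector(traj$states[, keep]),
      tau = tau)
  }
  list(spectra = do.call(rbind, spectra),
       trajectories = do.call(rbind, trajs))
}

#' Sweep of dynamical observables over reciprocal correlations
#'
#' For each (tau, realization) integrates one network and records the
#' maximal Lyapunov exponent (optional), participation ratio, activity
#' statistics, and convergence status. Seeds derive deterministically from
#' `root_seed` and the sweep indices, so identical specs give identical
#' tables.
#'
#' @param tau_grid Correlations.
#' @param geff Effective gain.
#' @param N Network size.
#' @param n_realizations Realizations per tau.
#' @param config A [sim_config()]; the observables use its windows.
#' @param root_seed Root seed.
#' @param lyapunov If TRUE also run the tangent-space exponent (roughly
#'   doubles the cost).
#' @return List with `runs` (one row per run) and `summary` (per-tau medians
#'   and standard errors, convergence counts).
#' @export
dynamics_sweep <- function(tau_grid, geff = 1.4, N = 500,
                           n_realizations = 20L,
                           config = sim_config(t_transient = 50,
                                               t_measure = 100,
                                               t_max = 150),
                           root_seed = 1L, lyapunov = TRUE) {
  rows <- list()
  for (ti in seq_along(tau_grid)) {
    tau <- tau_grid[ti]
    params <- ensemble_params(N = N, geff = geff, tau = tau, seed = root_seed)
    for (r in seq_len(n_realizations)) {
      run_seed <- mix_seed(root_seed, ti, r)
      W <- sample_weights(params, realization_index = r)
      traj <- integrate_network(W, config, draw_x0(N, config, run_seed))
      stats <- activity_stats(traj)
      pr <- if (traj$converged) NA_real_ else participation_ratio(traj)
      lam <- if (lyapunov)
        lyapunov_max(W, config, seed = run_seed) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, g = params$g, geff = geff, N = N, seed = run_seed,
        realization = r, lambda_max = lam, pr = pr, sigma = stats$sigma,
        sigma_n = stats$sigma_n, mean_sens = stats$mean_sensitivity,
        converged = traj$converged)
    }
  }
  runs <- do.call(rbind, rows)
  med_se <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    c(median(v), 1.2533 * sd(v) / sqrt(length(v)))
  }
  summ <- do.call(rbind, lapply(split(runs, runs$tau), function(d) {
    m <- vapply(d[c("lambda_max", "pr", "sigma", "sigma_n", "mean_sens")],
                med_se, numeric(2))
    data.frame(tau = d$tau[1], g = d$g[1], geff = d$geff[1], N = d$N[1],
               n_runs = nrow(d), n_converged = sum(d$converged),
               lambda_max_med = m[1, 1], lambda_max_se = m[2, 1],
               pr_med = m[1, 2], pr_se = m[2, 2],
               sigma_med = m[1, 3], sigma_se = m[2, 3],
               sigma_n_med = m[1, 4], sigma_n_se = m[2, 4],
               mean_sens_med = m[1, 5], mean_sens_se = m[2, 5])
  }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ[order(summ$tau), ])
}

#' Transient path-length sweep
#'
#' For each (tau, N, realization) integrates until convergence or `t_max`
#' and records the per-neuron path length. Non-convergent runs are censored
#' and excluded from the L summaries; their fraction is a first-class
#' output. Restricted to `tau >= 0`, where stable fixed points are actually
#' observed; medians and interquartile ranges are the primary summaries.
#'
#' @param tau_grid Correlations in `[0, 1]`.
#' @param geff Effective gain.
#' @param N_list Network sizes.
#' @param n_realizations Realizations per (tau, N) cell.
#' @param config A [sim_config()] with a generous `t_max`.
#' @param root_seed Root seed.
#' @return List with `runs` and per-cell `summary` (median, quartiles, mean
#'   of L over convergent runs; censoring fraction).
#' @export
path_length_sweep <- function(tau_grid = seq(0, 1, by = 0.2), geff = 1.2,
                              N_list = 300, n_realizations = 50L,
                              config = sim_config(t_max = 1000,
                                                  t_transient = 0,
                                                  t_measure = 1),
                              root_seed = 1L) {
  stopifnot(all(tau_grid >= 0), all(tau_grid <= 1))
  rows <- list()
  for (ni in seq_along(N_list)) for (ti in seq_along(tau_grid)) {
    N <- N_list[ni]; tau <- tau_grid[ti]
    params <- ensemble_params(N = N, geff = geff, tau = tau, seed = root_seed)
    for (r in seq_len(n_realizations)) {
      run_seed <- mix_seed(root_seed, ni, ti, r)
      W <- sample_weights(params, realization_index = r)
      traj <- integrate_network(W, config, draw_x0(N, config, run_seed))
      pl <- path_length(traj)
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, g = params$g, geff = geff, N = N, seed = run_seed,
        realization = r, L = pl$L, t_fp = pl$t_fp,
        converged = traj$converged, censored = pl$censored)
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(runs, interaction(runs$tau, runs$N, drop = TRUE)), function(d) {
      Lc <- d$L[!d$censored]
      data.frame(tau = d$tau[1], N = d$N[1], geff = d$geff[1],
                 n_runs = nrow(d), n_converged = sum(!d$censored),
                 censored_fraction = mean(d$censored),
                 L_median = if (length(Lc)) median(Lc) else NA_real_,
                 L_q1 = if (length(Lc)) quantile(Lc, 0.25, names = FALSE) else NA_real_,
                 L_q3 = if (length(Lc)) quantile(Lc, 0.75, names = FALSE) else NA_real_,
                 L_mean = if (length(Lc)) mean(Lc) else NA_real_)
    }))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ[order(summ$N, summ$tau), ])
}

#' Small-N fixed-point counts against the Kac-Rice determinant estimate
#'
#' Per network size: the mean fixed-point count over realizations
#' (exhaustive for N <= 3, Newton census — a lower bound — otherwise)
#' side by side with the Monte-Carlo `(1/N) log E|det(-I+W)|` estimate, for
#' trend comparison with `exp(N c)`.
#'
#' @param N_list Sizes (small; counting cost grows quickly).
#' @param g,tau Ensemble parameters.
#' @param M Realizations per size for counting and for the determinant MC.
#' @param seed Root seed.
#' @param n_starts Newton starts per realization when N > 3.
#' @return Data.frame with per-N mean counts, their standard errors, the
#'   determinant estimate and its stderr, and `census` flag (TRUE when the
#'   count is a Newton lower bound).
#' @export
fixed_point_count_sweep <- function(N_list = c(1, 2, 3), g = 1.5, tau = 0,
                                    M = 200L, seed = 1L, n_starts = 60L) {
  rows <- lapply(N_list, function(N) {
    params <- ensemble_params(N = N, g = g, tau = tau, seed = seed)
    counts <- vapply(seq_len(M), function(r) {
      W <- sample_weights(params, realization_index = r)
      if (N <= 3) count_fixed_points_exhaustive(W)
      else find_fixed_points(W, n_starts = n_starts,
                             seed = mix_seed(seed, N, r))$n_distinct
    }, numeric(1))
    kr <- kac_rice_mc(N, g, tau, M = max(M, 200L), seed = mix_seed(seed, N))
    data.frame(N = N, g = g, tau = tau, M = M,
               mean_count = mean(counts),
               se_count = sd(counts) / sqrt(M),
               log_mean_absdet_per_N = kr$log_mean_absdet_per_N,
               kr_stderr = kr$stderr,
               census = N > 3)
  })
  do.call(rbind, rows)
}
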