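# shared fixtures: all synthetic, built in code at test time

draw <- function(N, tau, g = NULL, geff = NULL, seed = 1L, realization = 1L,
                 diagonal_policy = "correlated_gaussian") {
  sample_weights(ensemble_params(N = N, g = g, geff = geff, tau = tau,
                                 seed = seed,
                                 diagonal_policy = diagonal_policy),
                 realization_index = realization)
}

# a hand-built trajectory object for observable closed-form checks
fake_trajectory <- function(states, dt = 0.1, t_transient = 0,
                            converged = FALSE) {
  times <- (seq_len(nrow(states)) - 1L) * dt
  derivs <- states * 0
  structure(list(times = times, states = states, derivs = derivs,
                 deriv_norms = rep(0, nrow(states)), deriv_norm_dt = dt,
                 t_end = max(times), converged = converged,
                 t_fp = if (converged) max(times) else NA_real_,
                 config = sim_config(dt = dt, t_transient = t_transient,
                                     t_measure = max(times, 1)),
                 W_params = NULL),
            class = "rnn_trajectory")
}

# folded-normal mean: E|w - 1| for w ~ Normal(0, s^2)
folded_mean_minus1 <- function(s) {
  s * sqrt(2 / pi) * exp(-1 / (2 * s^2)) + 2 * pnorm(1 / s) - 1
}
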