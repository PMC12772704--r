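test_that("uncoupled dynamics decay exactly and at 4th-order accuracy", {
  N <- 20
  x0 <- draw_x0(N, sim_config(), seed = 3)
  err_at <- function(dt) {
    cfg <- sim_config(dt = dt, t_max = 5, t_transient = 0, t_measure = 5)
    tr <- integrate_network(matrix(0, N, N), cfg, x0)
    xT <- tr$states[nrow(tr$states), ]
    max(abs(xT - x0 * exp(-tr$t_end)))
  }
  # norm halves every ln 2 time units
  cfg <- sim_config(dt = 0.05, t_max = 2 * log(2), t_transient = 0,
                    t_measure = 1)
  tr <- integrate_network(matrix(0, N, N), cfg, x0)
  iT <- nrow(tr$states)
  expect_equal(sqrt(sum(tr$states[iT, ]^2)),
               sqrt(sum(x0^2)) * exp(-tr$t_end), tolerance = 1e-6)
  # global error scales as dt^4 (ratio 16 per halving, within a factor of 4)
  errs <- vapply(c(0.1, 0.05, 0.025), err_at, numeric(1))
  expect_gt(errs[1] / errs[2], 16 / 4); expect_lt(errs[1] / errs[2], 16 * 4)
  expect_gt(errs[2] / errs[3], 16 / 4); expect_lt(errs[2] / errs[3], 16 * 4)
})

test_that("trajectories store the defining derivative and stop on convergence", {
  W <- draw(80, tau = 0, geff = 0.5, seed = 2)
  cfg <- sim_config(t_max = 100, t_transient = 0, t_measure = 1)
  x0 <- draw_x0(80, cfg, 2)
  tr <- integrate_network(W, cfg, x0)
  k <- nrow(tr$states) %/% 2L
  expect_equal(tr$derivs[k, ],
               -tr$states[k, ] + drop(W$values %*% tanh(tr$states[k, ])),
               tolerance = 1e-12)
  # below onset the origin attracts: convergence with tiny final norm
  expect_true(tr$converged)
  expect_true(is.finite(tr$t_fp))
  expect_lt(sqrt(sum(tr$states[nrow(tr$states), ]^2)), 1e-6 * sqrt(sum(x0^2)))
})

test_that("above onset at tau = 0 the network sustains fluctuations", {
  # positivity of the Lyapunov exponent is asserted at N = 1000 in the
  # acceptance suite; at this desk scale we check sustained fluctuations
  W <- draw(300, tau = 0, geff = 1.4, seed = 8)
  cfg <- sim_config(t_transient = 50, t_measure = 150, t_max = 200)
  tr <- integrate_network(W, cfg, draw_x0(300, cfg, 8))
  expect_false(tr$converged)
  expect_gt(activity_stats(tr)$sigma, 0.3)
})

test_that("the Jacobian matches its definition and its spectral edge", {
  W <- draw(30, tau = 0.2, g = 1, seed = 1)
  expect_equal(jacobian_at(W, rep(0, 30)), W$values - diag(30))
  x <- draw_x0(30, sim_config(), seed = 11)
  J <- jacobian_at(W, x)
  expect_equal(J, W$values %*% diag(1 - tanh(x)^2) - diag(30),
               tolerance = 1e-12)
  # saturation contracts: J -> -I
  Js <- jacobian_at(W, rep(50, 30))
  expect_equal(Js, -diag(30), tolerance = 1e-8)
  # elliptic-law edge of J at the origin: max Re eig ~ geff - 1
  Wb <- draw(1000, tau = 0.3, geff = 1.3, seed = 4)
  evJ <- eigen(jacobian_at(Wb, rep(0, 1000)), only.values = TRUE)$values
  expect_equal(max(Re(evJ)), 0.3, tolerance = 0.08)
})

test_that("the tangent-space exponent recovers linear-regime rates", {
  N <- 100
  cfg <- sim_config(t_transient = 5, t_measure = 60, t_max = 65)
  expect_equal(lyapunov_max(matrix(0, N, N), cfg, seed = 1), -1,
               tolerance = 1e-3)
  # below onset the exponent is the Jacobian edge geff - 1
  Wb <- draw(400, tau = 0, geff = 0.5, seed = 6)
  cfg2 <- sim_config(t_transient = 20, t_measure = 150, t_max = 170)
  expect_equal(lyapunov_max(Wb, cfg2, seed = 6), -0.5, tolerance = 0.05)
})

test_that("participation ratio has its closed-form values on synthetic modes", {
  T_ <- 400
  t_ <- seq_len(T_)
  one_mode <- outer(sin(t_ / 7), rnorm(12))
  expect_equal(participation_ratio(fake_trajectory(one_mode)), 1,
               tolerance = 1e-8)
  # k equal-variance orthogonal modes give PR = k
  k <- 4
  Q <- qr.Q(qr(matrix(rnorm(144), 12, 12)))[, 1:k]
  Z <- matrix(rnorm(T_ * k), T_, k)
  Z <- scale(Z, center = TRUE, scale = TRUE)
  Z <- Z %*% solve(chol(cov(Z)))  # exactly white
  Xk <- Z %*% t(Q)
  expect_equal(participation_ratio(fake_trajectory(Xk)), k, tolerance = 1e-6)
  # converged runs are refused without the explicit override
  tr_c <- fake_trajectory(one_mode, converged = TRUE)
  expect_error(participation_ratio(tr_c), "converged")
  expect_equal(participation_ratio(tr_c, allow_converged = TRUE), 1,
               tolerance = 1e-8)
  # zero-variance window is degenerate
  expect_true(is.na(participation_ratio(
    fake_trajectory(matrix(0, 50, 5), converged = TRUE),
    allow_converged = TRUE)))
})

test_that("activity statistics hit their saturation and quiescence limits", {
  quiet <- fake_trajectory(matrix(0, 50, 8))
  st <- activity_stats(quiet, g = 1.3)
  expect_equal(st$sigma, 0)
  expect_equal(st$sigma_n, 0)
  expect_equal(st$mean_sensitivity, 1)
  sat <- fake_trajectory(matrix(30, 50, 8))
  st2 <- activity_stats(sat, g = 1.3)
  expect_equal(st2$sigma_n, 1.3, tolerance = 1e-6)
  expect_lt(st2$mean_sensitivity, 1e-6)
})

test_that("path length reproduces the exponential-decay closed form", {
  N <- 50
  x0 <- draw_x0(N, sim_config(), 5)
  x0 <- x0 * sqrt(N) / sqrt(sum(x0^2))  # ||x0|| = sqrt(N) so L = 1
  run <- function(dt) {
    cfg <- sim_config(dt = dt, t_max = 60, t_transient = 0, t_measure = 1)
    path_length(integrate_network(matrix(0, N, N), cfg, x0))
  }
  pl <- run(0.05)
  expect_false(pl$censored)
  expect_equal(pl$L, 1, tolerance = 1e-3)
  # quadrature converges under step halving
  expect_lt(abs(run(0.025)$L - pl$L) / pl$L, 1e-3)
  # censoring, not an error, on non-convergent runs
  W <- draw(200, tau = 0, geff = 1.4, seed = 3)
  cfg <- sim_config(t_max = 60, t_transient = 0, t_measure = 1)
  plc <- path_length(integrate_network(W, cfg, draw_x0(200, cfg, 3)))
  expect_true(plc$censored)
  expect_true(is.na(plc$L))
})

test_that("Newton census finds the origin, the scalar triple, and honors the residual contract", {
  W <- draw(40, tau = 0.2, geff = 0.9, seed = 2)
  fp <- find_fixed_points(W, n_starts = 30, seed = 2)
  expect_gte(fp$n_distinct, 1L)
  expect_true(any(vapply(fp$points, function(p) all(p == 0), logical(1))))
  expect_true(all(fp$residuals < 1e-10))
  fp1 <- find_fixed_points(matrix(1.5, 1, 1), n_starts = 30, seed = 1)
  expect_equal(fp1$n_distinct,
               count_fixed_points_exhaustive(matrix(1.5, 1, 1)))
  # stability classification: for w = 1.5 the origin is the unstable root
  origin <- which(vapply(fp1$points, function(p) all(p == 0), logical(1)))
  expect_equal(fp1$n_unstable_dims[origin], 1L)
  expect_equal(sort(fp1$n_unstable_dims), c(0L, 0L, 1L))
})

test_that("unstable origin-Jacobian eigenvalues slow down as symmetry increases", {
  # vertical compression of the spectrum: mean |Im| over unstable modes
  # decreases with tau at fixed effective gain
  mean_im <- function(tau) {
    v <- vapply(1:3, function(s) {
      ev <- weight_spectrum(draw(600, tau = tau, geff = 1.2, seed = s))$eigenvalues
      un <- ev[Re(ev) > 1]
      if (!length(un)) return(NA_real_)
      mean(abs(Im(un)))
    }, numeric(1))
    mean(v, na.rm = TRUE)
  }
  ims <- vapply(c(-0.5, 0, 0.5), mean_im, numeric(1))
  expect_true(all(diff(ims) < 0))
})
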