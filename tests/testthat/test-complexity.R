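test_that("closed-form complexity handles both regimes and parameterizations", {
  # below onset the origin is the unique fixed point: c = 0
  r <- complexity_closed_form(g = 0.9, tau = 0)
  expect_true(r$below_onset)
  expect_equal(r$c, 0)
  expect_equal(r$c_contribution, 0)
  # at onset with independent weights c_raw vanishes exactly
  expect_equal(complexity_closed_form(geff = 1, tau = 0)$c_raw, 0)
  # frozen value computed independently by the log-potential quadrature
  expect_equal(complexity_closed_form(geff = 1.05, tau = -0.5)$c_raw,
               0.46869471434389, tolerance = 1e-10)
  # (g, tau) and (geff = g(1+tau), tau) agree; bitwise when the gain
  # round-trips exactly through binary arithmetic
  for (tau in c(0, 1, -0.5, -0.75)) {  # 1 + tau a power of two
    g <- 1.7
    a <- complexity_closed_form(g = g, tau = tau)
    b <- complexity_closed_form(geff = g * (1 + tau), tau = tau)
    expect_identical(a$c_raw, b$c_raw)
  }
  a <- complexity_closed_form(g = 2.3, tau = 0.37)
  b <- complexity_closed_form(geff = 2.3 * 1.37, tau = 0.37)
  expect_equal(a$c_raw, b$c_raw, tolerance = 1e-14)
  # tau = -1 at fixed g: raw expression divergent, but geff = 0 < 1
  d <- complexity_closed_form(g = 1.5, tau = -1)
  expect_true(d$divergent)
  expect_identical(d$c_raw, Inf)
  expect_equal(d$c, 0)
  expect_error(complexity_closed_form(geff = 1.2, tau = -1), "undefined")
})

test_that("complexity decreases in tau, diverges toward tau = -1, and is linear-onset for tau < 0", {
  taus <- seq(-0.95, 1, by = 0.05)
  cr <- complexity_closed_form(geff = 1.05, tau = taus)$c_raw
  expect_true(all(diff(cr) < 0))
  # divergence approaching full antisymmetry at fixed geff
  cr2 <- complexity_closed_form(geff = 1.05,
                                tau = c(-0.99, -0.999, -0.9999))$c_raw
  expect_true(all(diff(cr2) > 0))
  expect_gt(cr2[3], 3)
  # at onset the constant tau/2 - log(1+tau) survives for tau < 0
  for (tau in c(-0.8, -0.4, -0.1)) {
    c_on <- complexity_closed_form(geff = 1, tau = tau)$c_raw
    expect_equal(c_on, tau / 2 - log(1 + tau), tolerance = 1e-12)
    expect_gt(c_on, 0)
    # d c / d geff at onset equals -tau (first-order transition slope)
    h <- 1e-4
    slope <- (complexity_closed_form(geff = 1 + h, tau = tau)$c_raw -
              complexity_closed_form(geff = 1 - h, tau = tau)$c_raw) / (2 * h)
    expect_equal(slope, -tau, tolerance = 1e-3)
  }
})

test_that("onset is quadratic for independent weights", {
  for (eps in c(1e-2, 1e-3)) {
    ratio <- complexity_closed_form(geff = 1 + eps, tau = 0)$c_raw / eps^2
    expect_equal(ratio, 1, tolerance = 3 * eps)
  }
})

test_that("second-order onset expansion matches the closed form to cubic order", {
  expect_equal(onset_expansion(1.05, 0), 0.0025)
  expect_equal(onset_expansion(1, 0), 0)
  expect_identical(onset_expansion(1.05, -1), Inf)
  for (tau in c(-0.9, -0.5, 0, 0.5, 0.9)) {
    for (geff in c(1.02, 1.05)) {
      diff_ <- abs(onset_expansion(geff, tau) -
                   complexity_closed_form(geff = geff, tau = tau)$c_raw)
      expect_lt(diff_, 10 * (geff - 1)^3)
    }
  }
})

test_that("sign-change correlation solves c_raw = 0 and scales as 2(geff-1)^2", {
  ts <- sign_change_tau(1.05)
  expect_lt(abs(complexity_closed_form(geff = 1.05, tau = ts)$c_raw), 1e-8)
  expect_gt(complexity_closed_form(geff = 1.05, tau = ts / 2)$c_raw, 0)
  expect_lt(complexity_closed_form(geff = 1.05, tau = 2 * ts)$c_raw, 0)
  expect_lt(abs(sign_change_tau(1.01) / (2 * 1e-4) - 1), 0.2)
  expect_warning(expect_true(is.na(sign_change_tau(10))), "sign")
})

test_that("Kac-Rice MC matches the scalar folded-normal oracle and is overflow-safe", {
  kr <- kac_rice_mc(1, g = 1.5, tau = 0, M = 20000, seed = 2)
  expect_lt(abs(kr$log_mean_absdet_per_N - log(folded_mean_minus1(1.5))),
            3 * kr$stderr)
  # vanishing coupling: det(-I + W) -> -1, log-estimate -> 0
  kr0 <- kac_rice_mc(1, g = 1e-5, tau = 0, M = 200, seed = 2)
  expect_lt(abs(kr0$log_mean_absdet_per_N), 1e-4)
  # tau enters through the diagonal variance g^2(1+tau) for N = 1
  kr_t <- kac_rice_mc(1, g = 1.5, tau = 0.5, M = 20000, seed = 5)
  s <- 1.5 * sqrt(1.5)
  expect_lt(abs(kr_t$log_mean_absdet_per_N - log(folded_mean_minus1(s))),
            3 * kr_t$stderr)
  expect_error(kac_rice_mc(200, g = 1, tau = 0), "capped")
})

test_that("Kac-Rice MC is self-consistent across seeds at N = 30", {
  a <- kac_rice_mc(30, g = 1.5, tau = 0, M = 4000, seed = 1)
  b <- kac_rice_mc(30, g = 1.5, tau = 0, M = 4000, seed = 99)
  expect_lt(abs(a$log_mean_absdet_per_N - b$log_mean_absdet_per_N),
            3 * sqrt(a$stderr^2 + b$stderr^2))
})

test_that("exhaustive fixed-point counts reproduce the scalar bifurcation", {
  expect_equal(count_fixed_points_exhaustive(matrix(0.5, 1, 1)), 1L)
  expect_equal(count_fixed_points_exhaustive(matrix(1.5, 1, 1)), 3L)
  expect_equal(count_fixed_points_exhaustive(matrix(1 + 1e-9, 1, 1)), 1L)
  expect_error(count_fixed_points_exhaustive(diag(4)), "N <= 3")
  # E[count] at N=1: 1 + 2 P(w > 1), w ~ Normal(0, g^2(1+tau))
  p <- ensemble_params(N = 1, g = 1.5, tau = 0, seed = 7)
  counts <- vapply(1:2000, function(r)
    count_fixed_points_exhaustive(sample_weights(p, r)), numeric(1))
  target <- 1 + 2 * pnorm(1 / 1.5, lower.tail = FALSE)
  expect_lt(abs(mean(counts) - target), 3 * sd(counts) / sqrt(2000))
})

test_that("exhaustive and Newton counts agree on small coupled systems", {
  for (s in 1:5) {
    W <- draw(2, tau = 0.3, g = 2, seed = s)
    expect_equal(count_fixed_points_exhaustive(W),
                 find_fixed_points(W, n_starts = 150, start_radius = 3,
                                   seed = s)$n_distinct)
  }
})
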