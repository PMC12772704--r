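#' Closed-form topological complexity
#'
#' Topological complexity `c(g, tau)` is the exponential growth rate, with
#' network size N, of the expected number of fixed points of the tanh rate
#' network: `c = lim (1/N) log E[A_N]`. Above the onset of instability
#' (`geff = g (1 + tau) > 1`) the annealed Kac-Rice computation over the
#' elliptic spectral law gives the closed form
#'
#'   `c_raw = 1 / (2 g^2 (1 + tau)) - 1/2 + log g`.
#'
#' Below onset (`geff < 1`) the origin is the unique fixed point, so the
#' regime-aware value is `c = 0`; at or above onset `c = c_raw`. For
#' `tau > 0` near onset `c_raw` can be negative, in which case the
#' exponential estimate contributes nothing to the fixed-point count and
#' `c_contribution = max(0, c)` is reported (the true sub-exponential
#' complexity there is not captured by this estimate). As `tau -> -1` at
#' fixed `geff > 1` the complexity diverges; at `tau = -1` exactly (fixed
#' `g`) the raw expression is flagged divergent while `geff = 0 < 1` puts
#' the network below onset with a single fixed point, so `c = 0`.
#'
#' @param g Coupling gain(s), positive. Mutually exclusive with `geff`.
#' @param geff Effective gain(s) `g (1 + tau)`. Mutually exclusive with `g`;
#'   rejected at `tau = -1`.
#' @param tau Reciprocal correlation(s) in `[-1, 1]`. Recycled against the
#'   gain argument.
#' @return A data.frame with columns `g`, `tau`, `geff`, `c_raw`, `c`,
#'   `c_contribution`, `below_onset`, `divergent`.
#' @export
complexity_closed_form <- function(g = NULL, geff = NULL, tau) {
  if (is.null(g) == is.null(geff)) stop("supply exactly one of g and geff")
  stopifnot(all(is.finite(tau)), all(tau >= -1), all(tau <= 1))
  if (is.null(g)) {
    if (any(tau == -1))
      stop("geff cannot be supplied at tau = -1: g is undefined")
    stopifnot(all(is.finite(geff)), all(geff > 0))
    n <- max(length(geff), length(tau))
    geff <- rep_len(geff, n); tau <- rep_len(tau, n)
    g <- geff / (1 + tau)
  } else {
    stopifnot(all(is.finite(g)), all(g > 0))
    n <- max(length(g), length(tau))
    g <- rep_len(g, n); tau <- rep_len(tau, n)
    geff <- g * (1 + tau)
  }
  divergent <- tau == -1
  c_raw <- ifelse(divergent, Inf, 1 / (2 * g^2 * (1 + tau)) - 0.5 + log(g))
  below <- geff < 1
  cc <- ifelse(below, 0, c_raw)
  data.frame(g = g, tau = tau, geff = geff, c_raw = c_raw, c = cc,
             c_contribution = pmax(0, cc), below_onset = below,
             divergent = divergent)
}

#' Second-order onset expansion of the topological complexity
#'
#' The expansion of `c(geff, tau)` to second order in `geff - 1`:
#'
#'   `c ~ -(geff - 1) tau + (geff - 1)^2 (3 tau / 2 + 1) + tau/2 - log(1 + tau)`
#'
#' At `tau = 0` this reduces to `(geff - 1)^2`, the quadratic
#' (second-order-transition) onset of the uncorrelated ensemble; for
#' `tau < 0` the linear term dominates (first-order transition) and the
#' constant `tau/2 - log(1 + tau) > 0` survives at onset. Diverges at
#' `tau = -1`.
#'
#' @param geff Effective gain(s), near 1.
#' @param tau Reciprocal correlation(s) in `(-1, 1]`; `tau = -1` returns Inf.
#' @return Numeric vector of expansion values.
#' @export
onset_expansion <- function(geff, tau) {
  stopifnot(all(is.finite(geff)), all(is.finite(tau)),
            all(tau >= -1), all(tau <= 1))
  n <- max(length(geff), length(tau))
  geff <- rep_len(geff, n); tau <- rep_len(tau, n)
  eps <- geff - 1
  ifelse(tau == -1, Inf,
         -eps * tau + eps^2 * (1.5 * tau + 1) + tau / 2 - log(1 + tau))
}

#' Correlation at which the raw complexity changes sign
#'
#' For fixed `geff > 1`, `c_raw(geff, tau)` decreases in `tau` and crosses
#' zero at some `tau* > 0`; beyond it the exponential estimate is negative.
#' Near onset `tau* ~ 2 (geff - 1)^2`. Found by bracketed root search on
#' `(0, 1]` to absolute tolerance 1e-10 in `tau`.
#'
#' @param geff Effective gain, > 1.
#' @return The root `tau*`, or `NA` (with a warning) if `c_raw` does not
#'   change sign on `(0, 1]` (large `geff`).
#' @export
sign_change_tau <- function(geff) {
  stopifnot(length(geff) == 1L, is.finite(geff), geff > 1)
  h <- function(tau) {
    g <- geff / (1 + tau)
    1 / (2 * g^2 * (1 + tau)) - 0.5 + log(g)
  }
  if (h(1) > 0) {
    warning("c_raw does not change sign on (0, 1] at geff = ", geff)
    return(NA_real_)
  }
  # locate a positive lower bracket by coarse geometric scan toward 0
  lo <- 2 * (geff - 1)^2 / 8
  while (h(lo) <= 0 && lo > 1e-15) lo <- lo / 4
  if (h(lo) <= 0) stop("failed to bracket the sign change")
  uniroot(h, c(lo, 1), tol = 1e-10)$root
}

#' Monte-Carlo Kac-Rice determinant estimate
#'
#' Estimates `(1/N) log E|det(-I + W)|` over M independent draws of W; by
#' the Kac-Rice reduction this annealed determinant average carries the
#' exponential growth rate of the expected fixed-point count. Accumulation
#' is in the log domain (log-sum-exp of sign-magnitude log-determinants) and
#' the standard error of the log-mean comes from the delta method. The
#' annealed mean is dominated by rare large-determinant draws, so N is
#' capped: this is a small-N trend check, not a large-N estimator.
#'
#' @param N Matrix size, capped at 128.
#' @param g,tau Ensemble parameters.
#' @param M Number of realizations (>= 2).
#' @param seed Root seed.
#' @param diagonal_policy Passed to [ensemble_params()].
#' @return List with `N`, `M`, `log_mean_absdet_per_N`, `stderr`, `g`,
#'   `tau`, `seed`.
#' @export
kac_rice_mc <- function(N, g, tau, M = 1000L, seed = 1L,
                        diagonal_policy = "correlated_gaussian") {
  if (N > 128) stop("N capped at 128: the annealed |det| average is heavy-tailed")
  if (M < 2) stop("M must be >= 2")
  params <- ensemble_params(N = N, g = g, tau = tau, seed = seed,
                            diagonal_policy = diagonal_policy)
  logdets <- vapply(seq_len(M), function(m) {
    W <- sample_weights(params, realization_index = m)$values
    determinant(W - diag(N), logarithm = TRUE)$modulus
  }, numeric(1))
  mx <- max(logdets)
  y <- exp(logdets - mx)
  my <- mean(y)
  se_log <- sd(y) / (my * sqrt(M))
  list(N = as.integer(N), M = as.integer(M),
       log_mean_absdet_per_N = (mx + log(my)) / N,
       stderr = se_log / N, g = g, tau = tau, seed = as.integer(seed))
}

#' Exhaustively count fixed points of a tiny network
#'
#' Counts solutions of `-x + W tanh(x) = 0` for N <= 3 by brute force. All
#' fixed points satisfy `|x_i| <= sum_j |w_ij|`, so a dense grid of starts
#' over that box is refined by damped Newton iterations and the converged
#' roots are deduplicated. For N = 1 the roots are additionally bracketed by
#' sign changes on a fine grid (the scalar case `x = w tanh x` has 1 root
#' for `w <= 1` and 3 for `w > 1`).
#'
#' @param W A `weight_matrix` or plain matrix with N <= 3.
#' @param grid_points Grid resolution per dimension.
#' @return Integer count of distinct fixed points.
#' @export
count_fixed_points_exhaustive <- function(W, grid_points = NULL) {
  M <- if (inherits(W, "weight_matrix")) W$values else W
  if (!is.matrix(M)) M <- matrix(M, 1, 1)
  N <- nrow(M)
  if (N > 3) stop("exhaustive counting supports N <= 3; use find_fixed_points()")
  bound <- max(rowSums(abs(M))) + 0.5
  if (N == 1L) {
    w <- M[1, 1]
    f <- function(x) -x + w * tanh(x)
    xs <- seq(-bound, bound, length.out = 4001L)
    fx <- f(xs)
    roots <- xs[fx == 0]
    idx <- which(fx[-1] * fx[-length(fx)] < 0)
    for (k in idx) {
      roots <- c(roots, uniroot(f, c(xs[k], xs[k + 1]), tol = 1e-12)$root)
    }
    return(length(unique(round(roots / 1e-6)) ))
  }
  if (is.null(grid_points)) grid_points <- if (N == 2L) 15L else 9L
  axes <- replicate(N, seq(-bound, bound, length.out = grid_points),
                    simplify = FALSE)
  starts <- as.matrix(expand.grid(axes))
  roots <- list()
  for (s in seq_len(nrow(starts))) {
    r <- .newton_root(M, starts[s, ])
    if (!is.null(r)) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots)) return(0L)
  .dedupe_points(do.call(rbind, roots), tol = 1e-6)
}

# Damped Newton on F(x) = -x + W tanh(x); returns the root or NULL.
.newton_root <- function(W, x, max_iter = 80L, tol = 1e-12) {
  for (it in seq_len(max_iter)) {
    Fx <- -x + drop(W %*% tanh(x))
    nF <- max(abs(Fx))
    if (nF < tol) return(x)
    J <- -diag(length(x)) + W * rep(1 - tanh(x)^2, each = length(x))
    step <- tryCatch(solve(J, Fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      nFn <- max(abs(-xn + drop(W %*% tanh(xn))))
      if (nFn < nF || lam < 1e-4) break
      lam <- lam / 2
    }
    if (nFn >= nF && lam < 1e-4) return(NULL)
    x <- xn
  }
  NULL
}

.dedupe_points <- function(P, tol = 1e-6) {
  kept <- P[1, , drop = FALSE]
  for (i in seq_len(nrow(P))[-1]) {
    d <- sqrt(colSums((t(kept) - P[i, ])^2))
    if (all(d > tol)) kept <- rbind(kept, P[i, ])
  }
  nrow(kept)
}
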