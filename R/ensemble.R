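#' Parameters of a partially symmetric Gaussian connectivity ensemble
#'
#' Specifies one draw of an N-by-N Gaussian weight matrix with zero mean and
#' second moments `<w_ij w_kl> = (g^2/N) (d_ik d_jl + tau d_il d_jk)`: each
#' off-diagonal entry has variance `g^2/N` and the reciprocal pair
#' `(w_ij, w_ji)` has correlation `tau`. Exactly one of `g` (coupling gain)
#' and `geff` (effective gain, `geff = g * (1 + tau)`, the rightmost extent
#' of the limiting spectrum) must be supplied; the other is derived.
#'
#' @param N Network size (positive integer).
#' @param g Coupling gain (positive). Mutually exclusive with `geff`.
#' @param geff Effective gain `g * (1 + tau)` (positive). Mutually exclusive
#'   with `g`; rejected at `tau = -1` where `g` would be undefined.
#' @param tau Reciprocal correlation in `[-1, 1]`.
#' @param seed Non-negative integer root seed.
#' @param diagonal_policy `"correlated_gaussian"` (default) draws
#'   `w_ii ~ Normal(0, g^2 (1 + tau) / N)`, the variance the covariance
#'   structure prescribes at `i = j = k = l`; `"zero"` sets the diagonal to 0.
#' @return An object of class `ensemble_params`.
#' @export
ensemble_params <- function(N, g = NULL, geff = NULL, tau, seed = 1L,
                            diagonal_policy = c("correlated_gaussian", "zero")) {
  diagonal_policy <- match.arg(diagonal_policy)
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != round(N))
    stop("N must be a positive integer")
  if (length(tau) != 1L || !is.finite(tau) || tau < -1 || tau > 1)
    stop("tau must lie in [-1, 1]")
  if (is.null(g) == is.null(geff))
    stop("supply exactly one of g and geff")
  if (is.null(g)) {
    if (tau == -1)
      stop("geff cannot be supplied at tau = -1: g = geff/(1 + tau) is undefined")
    if (!is.finite(geff) || geff <= 0) stop("geff must be positive")
    g <- geff / (1 + tau)
  } else {
    if (!is.finite(g) || g <= 0) stop("g must be positive")
    geff <- g * (1 + tau)
  }
  if (length(seed) != 1L || !is.finite(seed) || seed < 0 || seed != round(seed))
    stop("seed must be a non-negative integer")
  structure(
    list(N = as.integer(N), g = g, geff = geff, tau = tau,
         seed = as.integer(seed), diagonal_policy = diagonal_policy),
    class = "ensemble_params")
}

#' @export
print.ensemble_params <- function(x, ...) {
  cat(sprintf(
    "ensemble_params: N=%d, g=%.6g, tau=%.3g (geff=%.6g), seed=%d, diagonal=%s\n",
    x$N, x$g, x$tau, x$geff, x$seed, x$diagonal_policy))
  invisible(x)
}

#' Sample a partially symmetric Gaussian weight matrix
#'
#' Draws `W` via the pairwise mixing `w_ij = (g/sqrt(N)) (alpha z_ij + beta
#' z_ji)` with independent standard Gaussians `z` and
#' `alpha = (sqrt(1+tau) + sqrt(1-tau))/2`,
#' `beta  = (sqrt(1+tau) - sqrt(1-tau))/2`, so that `alpha^2 + beta^2 = 1`
#' and `2 alpha beta = tau`: each off-diagonal entry is `Normal(0, g^2/N)`
#' and reciprocal pairs have correlation `tau`, with distinct unordered
#' pairs independent. The same mixing applied at `i = j` gives the
#' `correlated_gaussian` diagonal `w_ii ~ Normal(0, g^2 (1+tau)/N)`.
#'
#' Deterministic given `params$seed` and `realization_index`; distinct
#' realization indices use independent derived streams.
#'
#' @param params An [ensemble_params()] object.
#' @param realization_index Integer index of the realization (default 1).
#' @return A `weight_matrix` object: list with `values` (N-by-N matrix),
#'   `params`, and `realization_index`.
#' @export
sample_weights <- function(params, realization_index = 1L) {
  stopifnot(inherits(params, "ensemble_params"))
  N <- params$N
  tau <- params$tau
  alpha <- (sqrt(1 + tau) + sqrt(1 - tau)) / 2
  beta  <- (sqrt(1 + tau) - sqrt(1 - tau)) / 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(mix_seed(params$seed, 101L, realization_index))
  Z <- matrix(rnorm(N * N), N, N)
  W <- (params$g / sqrt(N)) * (alpha * Z + beta * t(Z))
  if (params$diagonal_policy == "zero") {
    diag(W) <- 0
  }
  # exact (anti)symmetry at the boundary correlations, untouched by rounding
  if (tau == 1) W <- (W + t(W)) / 2
  if (tau == -1) {
    W <- (W - t(W)) / 2
    diag(W) <- 0
  }
  structure(list(values = W, params = params,
                 realization_index = as.integer(realization_index)),
            class = "weight_matrix")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("weight_matrix: N=%d, g=%.6g, tau=%.3g, seed=%d, realization=%d\n",
              x$params$N, x$params$g, x$params$tau, x$params$seed,
              x$realization_index))
  invisible(x)
}

#' Pooled second-moment statistics of reciprocal weight pairs
#'
#' Estimates, pooled over realizations, the empirical mean and variance of
#' off-diagonal entries and the correlation of reciprocal pairs
#' `(w_ij, w_ji)` over all unordered pairs, with standard errors (Gaussian
#' approximations: `SE(var) = var * sqrt(2/(n-1))`,
#' `SE(corr) = (1 - corr^2)/sqrt(n_pairs)`).
#'
#' @param matrices A list of `weight_matrix` objects with identical params.
#' @return A list with `mean`, `var_offdiag`, `reciprocal_corr`, `n_pairs`,
#'   `stderr_var`, `stderr_corr`, and `degenerate` (TRUE when the entries
#'   have zero variance so the correlation is undefined, reported as NA).
#' @export
pair_statistics <- function(matrices) {
  if (length(matrices) < 1L) stop("need at least one matrix")
  stopifnot(all(vapply(matrices, inherits, logical(1), "weight_matrix")))
  p0 <- matrices[[1L]]$params
  same <- vapply(matrices, function(m) {
    p <- m$params
    p$N == p0$N && isTRUE(all.equal(p$g, p0$g)) &&
      isTRUE(all.equal(p$tau, p0$tau)) &&
      p$diagonal_policy == p0$diagonal_policy
  }, logical(1))
  if (!all(same)) stop("matrices have mixed ensemble parameters")
  N <- p0$N
  ut <- upper.tri(matrix(0, N, N))
  x <- unlist(lapply(matrices, function(m) m$values[ut]))
  y <- unlist(lapply(matrices, function(m) t(m$values)[ut]))
  entries <- c(x, y)
  n_pairs <- length(x)
  v <- if (length(entries) > 1) var(entries) else 0
  degenerate <- !is.finite(v) || v == 0
  rho <- if (degenerate || n_pairs < 2) NA_real_ else cor(x, y)
  list(mean = mean(entries),
       var_offdiag = v,
       reciprocal_corr = rho,
       n_pairs = n_pairs,
       stderr_var = v * sqrt(2 / max(1, length(entries) - 1)),
       stderr_corr = if (is.na(rho)) NA_real_ else (1 - rho^2) / sqrt(n_pairs),
       degenerate = degenerate)
}

#' Split a weight matrix into symmetric and antisymmetric parts
#'
#' `S = (W + t(W))/2`, `A = (W - t(W))/2`, with `W = S + A` exactly.
#'
#' @param W A `weight_matrix` or plain matrix.
#' @return List with components `symmetric` and `antisymmetric`.
#' @export
symmetry_split <- function(W) {
  M <- if (inherits(W, "weight_matrix")) W$values else W
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  list(symmetric = (M + t(M)) / 2, antisymmetric = (M - t(M)) / 2)
}
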