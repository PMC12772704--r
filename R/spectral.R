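#' Semi-axes of the limiting elliptic spectral law
#'
#' In the large-N limit the eigenvalues of a partially symmetric Gaussian
#' weight matrix are uniformly distributed on the ellipse with semi-axes
#' `a = g (1 + tau)` along the real axis and `b = g (1 - tau)` along the
#' imaginary axis. At `tau = 0` this is the circular law (disk of radius g);
#' at `tau = 1` the support collapses onto the real segment `[-2g, 2g]`
#' (semicircle law) and at `tau = -1` onto the imaginary segment.
#'
#' @param g Coupling gain (positive).
#' @param tau Reciprocal correlation in `[-1, 1]`.
#' @return An `ellipse_spec` list with `a`, `b`, `g`, `tau`.
#' @export
ellipse_axes <- function(g, tau) {
  stopifnot(length(g) == 1L, is.finite(g), g > 0,
            length(tau) == 1L, is.finite(tau), tau >= -1, tau <= 1)
  structure(list(a = g * (1 + tau), b = g * (1 - tau), g = g, tau = tau),
            class = "ellipse_spec")
}

#' Eigenvalues of a weight matrix
#'
#' Full (dense, generally nonsymmetric) eigendecomposition. The spectrum of
#' a real matrix is closed under complex conjugation.
#'
#' @param W A `weight_matrix` or plain square matrix.
#' @return A `spectrum` object: list with `eigenvalues` (complex vector of
#'   length N) and `params` (NULL for a plain matrix).
#' @export
weight_spectrum <- function(W) {
  M <- if (inherits(W, "weight_matrix")) W$values else W
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (!all(is.finite(M))) stop("matrix has non-finite entries")
  sym <- isSymmetric.matrix(M, tol = 0)
  ev <- eigen(M, symmetric = sym, only.values = TRUE)$values
  structure(list(eigenvalues = as.complex(ev),
                 params = if (inherits(W, "weight_matrix")) W$params else NULL),
            class = "spectrum")
}

#' Fraction of eigenvalues inside an inflated ellipse
#'
#' Finite-N check of the elliptic law: counts the fraction of eigenvalues
#' `u + iv` with `u^2/A^2 + v^2/B^2 <= 1` where `A = (1 + inflation) a`,
#' `B = (1 + inflation) b`. When the ellipse is degenerate (`b = 0` or
#' `a = 0`) the collapsed axis admits only a numerical tolerance.
#'
#' @param spec A `spectrum` object (or complex vector).
#' @param ellipse An [ellipse_axes()] result.
#' @param inflation Relative inflation of both semi-axes (default 0.05,
#'   accommodating finite-N edge fluctuations).
#' @return Fraction in `[0, 1]`.
#' @export
spectrum_support_check <- function(spec, ellipse, inflation = 0.05) {
  ev <- if (inherits(spec, "spectrum")) spec$eigenvalues else as.complex(spec)
  stopifnot(inherits(ellipse, "ellipse_spec"), inflation >= 0)
  A <- (1 + inflation) * ellipse$a
  B <- (1 + inflation) * ellipse$b
  u <- Re(ev); v <- Im(ev)
  tol <- 1e-8 * max(ellipse$g, 1)
  ru <- if (A > 0) (u / A)^2 else ifelse(abs(u) <= tol, 0, Inf)
  rv <- if (B > 0) (v / B)^2 else ifelse(abs(v) <= tol, 0, Inf)
  mean(ru + rv <= 1)
}

#' Logarithmic potential of the uniform elliptic law
#'
#' Numerical quadrature of `int log|z - w| rho(z) dz` where `rho` is the
#' uniform density on the ellipse with semi-axes `(a, b)`. In elliptical
#' polar coordinates `z = a r cos(t) + i b r sin(t)` the integral becomes
#' `(1/pi) int_0^1 r [ int_0^{2pi} log|z(r,t) - w| dt ] dr`; the logarithmic
#' singularity when `w` lies inside the support is integrable and handled by
#' splitting the radial integral at the level curve through `w` and the
#' angular integral at the singular angle. Degenerate supports (`b = 0` or
#' `a = 0`) use the 1-D semicircle marginal on the surviving axis.
#'
#' Evaluated at `w = 1` this is the large-N limit of
#' `(1/N) log E|det(-I + W)|`, the quantity the topological complexity
#' closed form expresses; the quadrature is the independent oracle for it.
#'
#' @param ellipse An [ellipse_axes()] result.
#' @param w Complex (or real) evaluation point.
#' @param rel.tol Quadrature tolerance passed to [stats::integrate()].
#' @return The potential (real scalar), to absolute accuracy ~1e-9.
#' @export
log_potential <- function(ellipse, w, rel.tol = 1e-11) {
  stopifnot(inherits(ellipse, "ellipse_spec"))
  a <- ellipse$a; b <- ellipse$b
  u0 <- Re(w); v0 <- Im(w)
  if (a == 0 && b == 0) stop("ellipse is a point")
  if (b == 0 || a == 0) {
    # support collapsed to a segment: the marginal of the uniform ellipse
    # along the surviving axis is the semicircle density (2/(pi s^2)) sqrt(s^2 - q^2)
    s <- max(a, b)
    along_real <- b == 0
    f <- function(q) {
      d2 <- if (along_real) (q - u0)^2 + v0^2 else u0^2 + (q - v0)^2
      0.5 * log(d2) * (2 / (pi * s^2)) * sqrt(pmax(0, s^2 - q^2))
    }
    pts <- sort(unique(c(-s, s, if (along_real && abs(u0) < s && v0 == 0) u0,
                         if (!along_real && abs(v0) < s && u0 == 0) v0)))
    tot <- 0
    for (k in seq_len(length(pts) - 1L)) {
      tot <- tot + integrate(f, pts[k], pts[k + 1L], rel.tol = rel.tol,
                             abs.tol = 1e-12, subdivisions = 400L)$value
    }
    return(tot)
  }
  # angular mean of log|z - w| on the scaled ellipse of parameter r
  ang <- function(r) {
    sing <- NULL
    # z(r, t) = w requires (u0/(a r))^2 + (v0/(b r))^2 = 1; locate t if so
    e <- (u0 / (a * r))^2 + (v0 / (b * r))^2
    if (abs(e - 1) < 1e-9) {
      sing <- atan2(v0 / (b * r), u0 / (a * r)) %% (2 * pi)
    }
    f <- function(t) {
      0.5 * log((a * r * cos(t) - u0)^2 + (b * r * sin(t) - v0)^2)
    }
    pts <- sort(unique(c(0, 2 * pi, sing)))
    tot <- 0
    for (k in seq_len(length(pts) - 1L)) {
      tot <- tot + integrate(f, pts[k], pts[k + 1L], rel.tol = rel.tol,
                             abs.tol = 1e-13, subdivisions = 400L)$value
    }
    tot
  }
  outer_f <- function(rv) vapply(rv, function(r) r * ang(r), numeric(1))
  # radial level r* at which the contour passes through w (kink of the
  # radial integrand); split there when it falls inside (0, 1)
  rstar <- sqrt((u0 / a)^2 + (v0 / b)^2)
  pts <- sort(unique(c(0, 1, if (rstar > 0 && rstar < 1) rstar)))
  tot <- 0
  for (k in seq_len(length(pts) - 1L)) {
    tot <- tot + integrate(outer_f, pts[k], pts[k + 1L], rel.tol = rel.tol,
                           abs.tol = 1e-12, subdivisions = 400L)$value
  }
  tot / pi
}
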