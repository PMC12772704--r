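---
title: "Complexity and dynamics of partially symmetric random recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity and dynamics of partially symmetric random recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recipnet)
```

## The model

`recipnet` studies the classical recurrent rate network of $N$ neurons with
membrane potentials $x_i(t)$,

$$\dot x_i = -x_i + \sum_{j=1}^N w_{ij}\, S(x_j), \qquad S(x) = \tanh(x),$$

with time in units of the membrane time constant. The synaptic weights are
jointly Gaussian with zero mean and second moments

$$\langle w_{ij} w_{kl} \rangle = \frac{g^2}{N}\left(\delta_{ik}\delta_{jl}
  + \tau\, \delta_{il}\delta_{jk}\right),$$

so each weight has variance $g^2/N$ and the two weights of a reciprocal
pair $(w_{ij}, w_{ji})$ have correlation $\tau \in [-1, 1]$: $\tau = 1$
gives a symmetric matrix, $\tau = -1$ an antisymmetric one, $\tau = 0$
independent entries. The gain $g$ sets the coupling strength.

Two questions organize the package. First, how does $\tau$ shape the
*topological complexity* — the exponential growth rate, with $N$, of the
expected number of fixed points of the dynamics? Second, how do changes in
that fixed-point landscape show up in observable dynamics: Lyapunov
exponents, dimensionality, activity statistics, and transient path
lengths?

## The connectivity ensemble

There is no external data anywhere in the package: the weight-matrix
generator *is* the data source, and it is first-class, tested code.
`sample_weights()` uses the pairwise mixing

$$w_{ij} = \frac{g}{\sqrt N}\left(\alpha z_{ij} + \beta z_{ji}\right),
\qquad
\alpha = \tfrac{1}{2}\!\left(\sqrt{1+\tau} + \sqrt{1-\tau}\right),\;
\beta = \tfrac{1}{2}\!\left(\sqrt{1+\tau} - \sqrt{1-\tau}\right),$$

with independent standard Gaussians $z$. Since $\alpha^2 + \beta^2 = 1$ and
$2\alpha\beta = \tau$, each off-diagonal entry is $\mathcal N(0, g^2/N)$
and reciprocal pairs have correlation exactly $\tau$, with distinct
unordered pairs independent. We chose this construction over an equivalent
matrix-level blend of symmetric and antisymmetric Gaussian matrices
because it makes the pair covariance transparent and testable pair by
pair (`pair_statistics()` recovers the moments within Monte-Carlo error).
At $\tau = \pm 1$ the (anti)symmetry is exact in floating point, not just
in distribution.

The covariance display evaluated at $i = j$ prescribes a diagonal variance
$g^2(1+\tau)/N$; the default `diagonal_policy = "correlated_gaussian"`
follows it literally. Because simulation conventions for the diagonal
differ across the field and are rarely stated, a `"zero"` policy is also
exposed; at the sizes used here the choice is immaterial to every
observable we compute.

Randomness is controlled by one root seed. Per-realization streams are
derived deterministically from (seed, realization index) by an integer
mixing function, so sweeps are reproducible and realizations independent
without any shared RNG state.

### What the generator does and does not emulate

The ensemble captures exactly one feature of biological connectivity:
pairwise reciprocal correlation. It is dense, sign-unconstrained (no
Dale's law), has no sparsity, no block or low-rank structure, and no
higher-order (e.g. cyclic) correlations. Tests passing on this ensemble
say nothing about real connectomes; they validate the theory on the
ensemble the theory is written for.

## Spectra and the elliptic law

In the large-$N$ limit the eigenvalues of $W$ fill, uniformly, the ellipse
with semi-axes $a = g(1+\tau)$ (real axis) and $b = g(1-\tau)$ (imaginary
axis) — circular law at $\tau = 0$, semicircle on $[-2g, 2g]$ at
$\tau = 1$, purely imaginary spectrum at $\tau = -1$. The origin of the
dynamics loses stability when the rightmost eigenvalue of $W$ exceeds 1,
i.e. at the *effective gain* $g_{\mathrm{eff}} \equiv g(1+\tau) = 1$; we
call this the onset. `ellipse_axes()`, `weight_spectrum()` and
`spectrum_support_check()` provide the law, finite-$N$ spectra, and
support checks (a 5% inflation of the ellipse absorbs finite-$N$ edge
fluctuations, which are material up to the $N \le 4000$ we compute
eigendecompositions for).

`log_potential()` evaluates the logarithmic potential
$\int \log|z - w|\, \rho_{g,\tau}(z)\, dz$ of the uniform elliptic law by
numerical quadrature, in elliptical polar coordinates where the domain is
a rectangle and the logarithmic singularity (for $w$ inside the support)
is integrable. The radial integral is split at the level curve through
$w$ and the angular integral at the singular angle; nested adaptive
quadrature then reaches absolute accuracies near $10^{-9}$, verified
against the disk closed form $|w|^2/(2g^2) - 1/2 + \log g$. Degenerate
supports ($\tau = \pm 1$) use the 1-D semicircle marginal. This quadrature
is deliberately independent of the complexity closed form below; it is the
oracle the closed form is tested against.

## Topological complexity

The expected number of fixed points $\mathbb E A_N$ grows like
$e^{N c}$ with

$$c(g, \tau) = \frac{1}{2 g^2 (1+\tau)} - \frac12 + \log g,$$

valid above onset. The derivation runs through the Kac–Rice formula: the
expected count reduces (up to subexponential factors) to
$\mathbb E\left|\det(-\mathbb I + W)\right|$, whose normalized logarithm
converges to the log-potential of the elliptic law at $w = 1$ — which is
exactly the expression above. `complexity_closed_form()` evaluates it;
the equality with `log_potential(ellipse_axes(g, tau), 1)` to $10^{-6}$
across a grid of $(g_{\mathrm{eff}}, \tau)$ is an acceptance-level test.
Note the equality requires $w = 1$ *inside* the spectral support, i.e.
$g_{\mathrm{eff}} > 1$; outside the support the potential flattens to that
of a point mass and the closed form no longer applies.

Regime logic, all exposed in the returned table:

* **Below onset** ($g_{\mathrm{eff}} < 1$): the dynamics are contracting
  and the origin is the unique fixed point, so the regime-aware value is
  $c = 0$ regardless of the analytic expression (`c_raw`). At $\tau = -1$
  with fixed $g$ the raw expression diverges, but
  $g_{\mathrm{eff}} = 0$: the network is below onset and $c = 0$ — the
  divergence is meaningful only for $\tau \to -1$ at fixed
  $g_{\mathrm{eff}} > 1$.
* **Onset expansion**: to second order in $g_{\mathrm{eff}} - 1$,
  $c \approx -(g_{\mathrm{eff}}-1)\tau +
  (g_{\mathrm{eff}}-1)^2(\tfrac{3\tau}{2}+1) + \tfrac{\tau}{2} -
  \log(1+\tau)$ (`onset_expansion()`). At $\tau = 0$ this is the quadratic
  onset $(g_{\mathrm{eff}}-1)^2$ (a second-order transition); for
  $\tau < 0$ the linear term and the positive constant
  $\tau/2 - \log(1+\tau)$ make the transition first-order, and the
  complexity diverges as $\tau \to -1$.
* **Positive correlations**: just above onset, `c_raw` turns negative for
  $\tau$ beyond a root $\tau^*$ (`sign_change_tau()`, bracketed bisection
  to $10^{-10}$; $\tau^* \to 2(g_{\mathrm{eff}}-1)^2$ at onset). There the
  exponential estimate contributes nothing — `c_contribution = max(0, c)`
  — and the true, subexponential complexity is not described by this
  theory; the package reports the raw value with that flag rather than
  modeling the correction.

`kac_rice_mc()` estimates $(1/N)\log \mathbb E|\det(-\mathbb I + W)|$ by
Monte Carlo in the log domain (log-sum-exp of LU log-determinants, delta-
method standard errors). The annealed average is dominated by rare draws
and its variance grows quickly with $N$, so the function refuses
$N > 128$: it is a small-$N$ trend check, validated at $N = 1$ against
the folded-normal closed form
$\mathbb E|w - 1| = s\sqrt{2/\pi}\, e^{-1/(2s^2)} + 2\Phi(1/s) - 1$,
$s^2 = g^2(1+\tau)$. `count_fixed_points_exhaustive()` (dense grid
bracketing plus Newton refinement, $N \le 3$) and `find_fixed_points()`
(damped Newton census with analytic Jacobian, deduplication at $10^{-6}$,
odd-symmetry mirroring, residual contract
$\|{-x^* + W\tanh x^*}\|_\infty < 10^{-10}$) provide direct counts. A
caution established by the small-$N$ experiments
(`fixed_point_count_sweep()`, `analysis/05_smallN_counting.R`): at fixed
$g$, *typical* small-$N$ counts are dominated by the distance from onset
and can order opposite to $c$ across $\tau$; the annealed determinant
rate, which is what $c$ describes, orders correctly already at $N = 8$.

## Dynamics and observables

`integrate_network()` integrates the rate equation with a classical
fixed-step 4th-order scheme, default $dt = 0.05$. The vector field is
smooth and bounded, a fixed step makes trajectories bit-reproducible, and
the $dt^4$ global-error scaling is verified on the uncoupled closed form
$x(t) = x_0 e^{-t}$. Convergence to a fixed point is declared when
$\|\dot x\|/\sqrt N$ (per-neuron normalized, hence $N$-independent) stays
below $10^{-9}$ for 5 consecutive checks spaced one time unit; $t_{fp}$ is
the first crossing. One caveat for strongly antisymmetric coupling at
fixed $g_{\mathrm{eff}}$: $g = g_{\mathrm{eff}}/(1+\tau)$ grows as
$\tau \to -1$ and with it the spectral extent $b = g(1-\tau)$ along the
imaginary axis, i.e. the fastest oscillation frequencies. The default step
resolves $b\,dt \lesssim 1.3$ at the most extreme sweep point we ship
($\tau = -0.9$, $g_{\mathrm{eff}} = 1.4$); we verified the reported
observables there against $dt$ down to $0.004$ and against an independent
adaptive integrator, and they agree to plotting accuracy.

Observables:

* `lyapunov_max()`: Benettin tangent-space method — one tangent vector
  co-integrated under $\dot v = J(x(t))v$ with
  $J = -\mathbb I + W\,\mathrm{diag}(1-\tanh^2 x)$, renormalized every 1
  time unit, log stretch factors averaged after the transient. Tangent
  space avoids the nonlinearity contamination of finite trajectory
  separations. Defaults discard $t = 100$ and measure for $t = 1000$;
  the shipped sweeps use shorter windows (stated below).
* `participation_ratio()`: $(\sum_i \mu_i)^2 / \sum_i \mu_i^2$ over
  eigenvalues of the time covariance of the measurement window
  (mean-subtracted per neuron; computed from singular values of the
  centered sample matrix). Equals the number of equal-variance modes on
  synthetic data; undefined (NA) at a fixed point.
* `activity_stats()`: time averages of the population activity scale
  $\sigma(t) = (N^{-1}\sum_j x_j^2)^{1/2}$, the mean-field drive scale
  $\sigma_n(t) = g\,(N^{-1}\sum_j S^2(x_j))^{1/2}$, and the mean
  sensitivity $N^{-1}\sum_j S'(x_j)$.
* `path_length()`: $L = N^{-1/2}\int_0^{t_{fp}} \|\dot x\|\,dt$ by
  trapezoidal quadrature of per-step derivative norms (the uncoupled
  closed form $L = 1$ for $\|x_0\| = \sqrt N$ is matched to $10^{-3}$).
  Non-convergent runs are *censored*, never errors: sweep summaries
  report medians and interquartile ranges over convergent runs together
  with the censoring fraction, and runs with $\tau < 0$ are excluded by
  design since stable fixed points are essentially never observed there.

Initial conditions are Gaussian, $x_{0,i} \sim \mathcal N(0, 1)$ by
default; none of the integration settings were stated by the theory this
package implements, so all are exposed in `sim_config()`.

## Problem sizes in the shipped tests and sweeps

Full-scale curves (e.g. $N = 2000$ with 200 realizations) are
config-selectable but deliberately not what the test suite runs. The
shipped desk-scale choices: moment recovery at $N = 200$ with 100
realizations; spectral-edge checks on single $N = 4000$ draws; Lyapunov
checks at $N = 1000$ (one realization each for the below-onset rate
$g_{\mathrm{eff}} - 1$ and for positivity at $g_{\mathrm{eff}} = 1.4$);
the $\sigma$/sensitivity sweep at $N = 500$, 20 realizations, transient
50, window 100; the path-length sweep at $N = 300$, 50 realizations,
$t_{\max} = 1000$ (chosen once to balance the censoring fraction — 74%
at $\tau = 0$ down to 28% at $\tau = 1$ — against runtime); relaxation
checks at $\tau = 1$, $N = 300$, $t_{\max} = 2000$.

## What reproduces and what does not

With those sizes the package reproduces: the monotone decrease and
$\tau \to -1$ divergence of $c$; the oracle equivalence of closed form
and quadrature; the quadratic ($\tau = 0$) versus first-order
($\tau < 0$) onset; the elliptic/circular/semicircle spectral edges at
$N = 4000$ within stochastic edge fluctuations; the below-onset Lyapunov
rate and above-onset chaos at $\tau = 0$; vertical spectral compression
(unstable eigenvalues' imaginary parts shrinking with $\tau$); the
decrease of median path length with $\tau$ and universal relaxation at
$\tau = 1$; and the interior maximum of the participation ratio near
$\tau \approx -0.75$ at $g_{\mathrm{eff}} = 1.4$.

Two qualitative claims about the strongly antisymmetric regime do *not*
reproduce in these simulations, at any $N \le 2000$, $dt \ge 0.004$, or
initial-condition scale we probed (including starts aligned with the top
eigenvector of the symmetric part, and cross-checked with an independent
adaptive integrator): a sharp rise of $\sigma$ and a sharp fall of the
mean sensitivity for $\tau < -0.6$ at fixed $g_{\mathrm{eff}} = 1.4$. In
our runs the strongly antisymmetric network settles into fast,
low-amplitude chaotic oscillations: $\sigma$ stays near 0.6–0.8 and the
sensitivity near 0.8, even as $\sigma_n$ grows like $g$ (which we do
reproduce). A saturated high-$\sigma$ state would have to satisfy
$x = W S(x)$ with strongly aligned $x$ and $S(x)$, which the antisymmetric
part of $W$ penalizes — at $\tau = -1$ exactly, $u^\top W u = 0$ makes
such states impossible. The corresponding expectations are encoded
faithfully in the acceptance tests and left failing rather than loosened;
treat the $\tau \lesssim -0.7$ behavior of $\sigma$ and the sensitivity
as an open discrepancy between the annealed theory's narrative and direct
simulation at these sizes.

## Known limitations

* The closed form is annealed: quenched (typical-realization) complexity,
  stability indices of the counted fixed points, and the subexponential
  corrections relevant for $\tau > \tau^*$ are out of scope.
* `kac_rice_mc()` cannot follow the annealed average to large $N$
  (heavy-tailed summands); it validates trends, not the limit.
* `find_fixed_points()` is a census: a lower bound that degrades as the
  landscape grows; exhaustive counting is restricted to $N \le 3$.
* Eigendecompositions are dense and capped in practice near $N = 4000$
  by desk-scale runtimes.
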