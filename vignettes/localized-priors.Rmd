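---
title: "Receptive-field estimation with localized priors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptive-field estimation with localized priors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldrf)
```

## The model

A neuron's linear receptive field (RF) `w` maps a stimulus vector to the
expected response in a time bin. `aldrf` works with the linear-Gaussian
encoding model

    y_t = x_t' w + eps_t,   eps_t ~ N(0, sigma^2),

where `x_t` is the spacetime stimulus preceding bin `t`. The maximum
likelihood estimate, `(X'X)^{-1} X'y`, is the whitened spike-triggered
average; it converges slowly in high dimension and is badly corrupted by
high-frequency noise under naturalistic (1/F) stimuli, whose designs are
ill-conditioned.

Regularization enters as a zero-mean Gaussian prior `w ~ N(0, C(theta))`.
The posterior is then Gaussian with

    Lambda = (X'X / sigma^2 + C^{-1})^{-1},   mu = Lambda X'y / sigma^2,

and the marginal likelihood (evidence) of the hyperparameters,
`p(y | X, theta, sigma^2) = N(y; 0, X C X' + sigma^2 I)`, is available in
closed form. Empirical Bayes proceeds in two stages: maximize the
evidence over `(theta, sigma^2)`, then report the posterior under the
estimated prior. The noise variance is treated as an extra
hyperparameter and maximized jointly, never integrated out.

Everything is computed from the sufficient statistics `X'X`, `X'y`,
`y'y`, `n`, so the cost of hyperparameter search does not grow with the
amount of data.

## Prior families

All scale hyperparameters enter as `exp(-rho)`, a log precision, so
optimization is unconstrained in sign. Filter coefficients are
enumerated row-major over the grid (last axis fastest) with 0-based
pixel coordinates; both conventions are fixed for reproducibility.

* **ridge** — `C = exp(-rho) I`: i.i.d. shrinkage.
* **ARD** — a separate variance `exp(-rho_i)` per coefficient; evidence
  optimization drives irrelevant variances to zero, giving sparsity.
* **ASD** — a dense Gaussian kernel,
  `C_ij = exp(-rho - sum_a D_ij,a^2 / (2 delta_a^2))`, one smoothness
  scale per axis: correlations decay with pixel distance, giving smooth
  estimates.
* **ALDs** — a *localized* diagonal prior: the variance of coefficient
  `i` is a Gaussian profile in its Mahalanobis distance from a region
  center, `C_ii = exp(-rho_s - (chi_i - nu_s)' Psi_s^{-1} (chi_i - nu_s)/2)`.
  Coefficients outside the inferred elliptical region get vanishing
  variance and are pruned (their posterior is a delta at zero). When the
  region grows much larger than the grid the profile flattens and ALDs
  reduces to ridge.
* **ALDf** — the same construction in the real orthogonal Fourier basis,
  over componentwise frequency magnitudes `|omega|`, which enforces the
  reflection symmetry `C(omega) = C(-omega)` required of a real filter's
  transform. RFs respond only over a limited frequency band, so this
  encodes smoothness *and* band selection (unlike ASD, it can suppress
  the DC and low frequencies too).
* **ALDsf** — both localities in series through the sandwich covariance
  `C = M_s B' C_f B M_s`, with `M_s` the square root of the ALDs
  diagonal, `C_f` the ALDf diagonal, and `B` the orthogonal DFT basis.
  The matrix is kept in factored form. With broad regions it defaults to
  ALDf, ALDs, or ridge — it never does worse than the simpler prior the
  data support.

The Mahalanobis exponent carries the conventional factor 1/2; any other
constant convention is absorbed by a rescaling of `Psi`. `Psi` matrices
are parameterized directly by their `d(d+1)/2` symmetric entries;
feasibility (positive definiteness) is checked by factorization, and the
optimizer treats infeasible proposals through a smooth minimum-eigenvalue
penalty rather than an error. We considered and rejected a triangular
factor reparameterization: direct entries keep the coarse initialization
grids and bound constraints interpretable in pixel units.

The componentwise absolute value in ALDf is one of two defensible
readings of frequency-reflection symmetry; a signed form that preserves
quadrant (orientation) information is noted as future work.

## Numerical strategy

Nearly singular prior covariances are the *normal* operating regime
(that is what pruning and smoothness mean), so `C` is never inverted.
With a factor `S` such that `C = S S'` and
`A = I + S' X'X S / sigma^2` (well-conditioned by construction):

    log evidence = -1/2 [ n log(2 pi sigma^2) + log det A
                          + (y'y - b' A^{-1} b / sigma^2) / sigma^2 ],
    mu = S A^{-1} b / sigma^2,   Lambda = S A^{-1} S',   b = S' X'y.

All solves are triangular (Cholesky); a single jitter of
`1e-10 trace/D` is added if a factorization fails once, and a second
failure is an error. Directions whose prior variance falls below
`1e-10` of the maximum are pruned from the active set, which speeds the
algebra up substantially as a localized fit converges; pruning at this
threshold moves the evidence by well under `1e-6`. Re-expansion of
pruned coefficients within a fit is not performed.

Evidence gradients are analytic, assembled by the chain rule through
`dC/dtheta` for every family. The Hessian is obtained by central
differencing of the analytic gradient: it is only used for the
Metropolis-Hastings proposal scale and for diagnostics, and
differencing an exact gradient is accurate to second order there, while
the closed-form second-derivative expressions would add considerable
surface area for no accuracy the package needs.

Fixed-point estimation (ridge, ARD) uses the effective
degrees-of-freedom updates with convergence tolerance `1e-6` (relative)
and iteration caps of 200/500. Quasi-Newton estimation (ASD, ALD
variants) uses bound-constrained L-BFGS with projected-gradient
tolerance `1e-3` and an iteration cap of 150; the best feasible point
encountered is returned, so the fit never reports less evidence than
its initialization. Bounds are deliberately loose: `rho` in
[-20, 20], region centers within one grid length of the grid, `Psi`
diagonals in `[1e-4, (4 m_a)^2]`, ASD length scales in `[0.05, 4 m_a]`,
and `sigma^2` within `[1e-8, 10] var(y)`.

Initialization matters because the evidence is not concave in the
hyperparameters. ALDs starts from the ridge fit's noise variance and
the center of mass of the absolute ridge estimate, with `Psi` chosen
from five log-spaced diagonal widths (8%–250% of the grid, ties broken
by first maximum) scored by evidence; ALDf uses the centroid of the
ridge estimate's Fourier power analogously. ALDsf concatenates the two
individually fitted blocks and then line-searches a shared scale offset,
because the product of two separately calibrated scale factors would
over-shrink the combined prior.

## Fully Bayesian inference

Empirical Bayes conditions on the hyperparameter point estimate and so
understates uncertainty when the evidence surface is flat. The
`mh_hyperposterior()` sampler runs a random-walk Metropolis-Hastings
chain over `(theta, sigma^2)` whose target is the evidence times a
uniform hyperprior over the optimization box. The isotropic proposal
standard deviation comes from the largest eigenvalue of the inverse
Hessian of the log evidence at the mode — since that Hessian is
negative definite, this is the inverse curvature of the *stiffest*
direction, which keeps acceptance workable; a per-axis diagonal scaling
is available behind a flag, off by default. One filter sample is drawn
from the conditional Gaussian posterior per state; their mean is the
Bayes least-squares estimate and their interpolated empirical quantiles
give credible intervals (burn-in defaults to 10% of the chain). A
single seeded generator drives proposals, acceptance draws and filter
draws in that fixed order, so traces are bitwise reproducible.

On simulated data the FB intervals are wider than the EB intervals for
small datasets and the two converge as data accumulate, while the FB
and EB point estimates are nearly identical throughout — the practical
reason `aldrf` defaults to empirical Bayes.

## What the simulations emulate

`make_filter()` supplies the standard menagerie: an oriented Gabor (V1
simple cell; default envelope sd of a quarter grid length so the filter
spans most of the patch, carrier 0.25 cycles/pixel at 45 degrees), a
center-surround difference of Gaussians (retinal ganglion cell), a
grid-cell filter (three plane waves at 60 degree spacings — localized in
frequency but not space), circularly windowed white noise (localized in
space but not frequency), and pure white noise (localized in neither).
`gen_stimuli()` provides white Gaussian, binary, and 1/F Gaussian
ensembles; the 1/F field has Fourier amplitude proportional to `1/f`
(power `1/f^2`, the exponent is configurable), DC amplitude clamped to
the lowest nonzero frequency, and unit marginal variance.
`simulate_scenario()` rescales the true filter to unit signal variance
and adds noise of variance 0.3 by default.

Benchmarks use the normalized squared filter error
`||k_hat - k||^2 / ||k||^2` and summarize methods by geometric-mean
error ratios against a reference, which makes the conclusions invariant
to the error normalization. The acceptance script
(`scripts/acceptance.R`) regenerates the headline benchmark at desk
scale: a 16x16 Gabor under 1/F stimuli, training sizes 500–4000, twenty
datasets per size — problem sizes chosen so the full benchmark runs in
minutes on one core while leaving the qualitative ordering (ALDsf
ahead of ASD ahead of ridge and ML) clearly resolved.

These simulations satisfy the linear-Gaussian model exactly. Real
recordings do not: spiking noise is non-Gaussian, responses pass
through output nonlinearities, and recordings are non-stationary (the
block resampler exists to blunt the latter). Passing benchmarks here
therefore demonstrates correct inference under the model and the
relative merits of the priors, not performance guarantees for any
particular preparation.

## Worked example

```{r example, eval = FALSE}
grid <- filter_grid(c(16, 16))
sc <- simulate_scenario("gabor", "one_over_f", n = 1000, grid, seed = 1)
ss <- sufficient_stats(sc$X, sc$y)

fits <- list(
  ml    = ald_fit(ss, shape = grid, family = "ml"),
  ridge = ald_fit(ss, shape = grid, family = "ridge"),
  asd   = ald_fit(ss, shape = grid, family = "asd"),
  aldsf = ald_fit(ss, shape = grid, family = "aldsf")
)
sapply(fits, function(f) filter_error(sc$w, f$estimate))
```

## Known limitations

Only the linear-Gaussian likelihood is supported: no Poisson or
point-process observation models, and no multi-filter (complex-cell)
extensions. The dense Fourier basis and `O(D^3)` evidence algebra are
comfortable up to a few thousand coefficients; beyond that, pruning
carries most of the load and very non-local filters become expensive.
The symmetric product-of-Gaussians alternative to the sandwich
combination is documented but not implemented. File containers use
R-native serialization plus text sidecars; no neurophysiology file
formats are parsed.
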