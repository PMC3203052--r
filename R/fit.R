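# Empirical-Bayes hyperparameter estimation.
#
# Ridge and ARD use the classical effective-degrees-of-freedom fixed-point
# updates; ASD and the ALD variants maximize the log evidence with
# bound-constrained L-BFGS using the analytic gradient. Initialization
# follows the center-of-mass / Fourier-power-centroid heuristics, seeded
# from the ridge fit.

.fit_result <- function(family, theta, noise_var, posterior, trace, init,
                        d = NULL, D = NULL, extra = list()) {
  hp <- hyperparams(family, theta, noise_var, d = d, D = D)
  structure(c(list(hyperparams = hp, posterior = posterior,
                   trace = trace, init = init,
                   estimate = posterior$mean), extra),
            class = "ald_fit")
}

#' @export
print.ald_fit <- function(x, ...) {
  cat("<ald_fit>", x$hyperparams$family,
      " log evidence =", format(x$posterior$log_evidence),
      " sigma^2 =", format(x$hyperparams$noise_var),
      " iterations =", length(x$trace), "\n")
  invisible(x)
}

# variance of y implied by the sufficient statistics (responses are treated
# as centered, consistent with the zero-mean linear-Gaussian model)
.response_var <- function(ss) ss$yty / ss$n

# ridge-regularized pilot solve, used only to scale initial values when the
# plain ML solve is unavailable (n < D or ill-conditioned designs)
.pilot_estimate <- function(ss) {
  est <- tryCatch(ml_estimate(ss), error = function(e) NULL)
  if (!is.null(est)) return(est)
  lam0 <- sum(diag(ss$xtx)) / ss$D
  drop(solve(ss$xtx + diag(lam0, ss$D), ss$xty))
}

#' Empirical-Bayes ridge regression
#'
#' Alternates the effective-degrees-of-freedom fixed-point updates for the
#' ridge precision `lambda = exp(rho)` and the noise variance:
#' `gamma = D_active - lambda tr(Lambda)`, `lambda <- gamma / mu'mu`,
#' `sigma^2 <- RSS / (n - gamma)`, recomputing the posterior after every
#' update. Initialized at `sigma^2 = 0.1 var(y)` and `lambda` such that the
#' prior variance matches the variance of a pilot (ML) estimate.
#'
#' @param ss an [sufficient_stats()] object.
#' @param tol relative convergence tolerance on `(lambda, sigma^2)`.
#' @param maxit maximum number of fixed-point iterations.
#' @return An object of class `ald_fit` with fields `hyperparams`,
#'   `posterior`, `trace` (per-iteration log evidence), `init`, `estimate`.
#' @export
fit_ridge_eb <- function(ss, tol = 1e-6, maxit = 200) {
  stopifnot(inherits(ss, "ald_suffstats"), ss$n > 1)
  vy <- .response_var(ss)
  s2 <- 0.1 * vy
  w0 <- .pilot_estimate(ss)
  v0 <- max(mean(w0^2), 1e-12 * vy, .Machine$double.eps)
  lam <- 1 / v0
  trace <- numeric(0)
  init <- list(noise_var = s2, lambda = lam)
  for (it in seq_len(maxit)) {
    prior <- ridge_cov(log(lam), ss$D)
    res <- .ald_core(prior, ss, s2, need = "posterior")
    trace <- c(trace, res$log_evidence)
    tr_lambda <- sum(res$cov_diag)
    gam <- ss$D - lam * tr_lambda
    mu2 <- sum(res$mean^2)
    lam_new <- if (mu2 > 0) gam / mu2 else lam * 10
    s2_new <- res$rss / max(ss$n - gam, 1e-8)
    if (!is.finite(lam_new) || lam_new <= 0 || !is.finite(s2_new) ||
        s2_new <= 0) {
      stop("ridge fixed-point diverged (lambda = ", format(lam_new),
           ", sigma^2 = ", format(s2_new), ") after ", it, " iterations")
    }
    done <- abs(lam_new - lam) < tol * abs(lam) &&
      abs(s2_new - s2) < tol * abs(s2)
    lam <- lam_new
    s2 <- s2_new
    if (done) break
  }
  prior <- ridge_cov(log(lam), ss$D)
  post <- posterior_moments(ss, prior, s2, cov = FALSE)
  .fit_result("ridge", c(rho = log(lam)), s2, post, trace, init, D = ss$D)
}

#' Empirical-Bayes automatic relevance determination
#'
#' Per-coefficient precision updates `alpha_i <- (1 - alpha_i Lambda_ii) /
#' mu_i^2` with the matching noise-variance update; coefficients whose
#' prior variance falls below `prune_threshold` times the maximum are
#' removed from the active set (their posterior becomes a delta at zero).
#' Initialized from the maximum-evidence ridge fit.
#'
#' @param ss an [sufficient_stats()] object.
#' @param init a ridge `ald_fit` used for initialization; computed if
#'   `NULL`.
#' @param tol relative convergence tolerance.
#' @param maxit maximum iterations.
#' @param prune_threshold relative prior-variance pruning threshold.
#' @return An `ald_fit`; `hyperparams$theta` holds per-coefficient log
#'   precisions (pruned coefficients at `Inf`).
#' @export
fit_ard_eb <- function(ss, init = NULL, tol = 1e-6, maxit = 500,
                       prune_threshold = 1e-10) {
  stopifnot(inherits(ss, "ald_suffstats"))
  if (is.null(init)) init <- fit_ridge_eb(ss)
  lam0 <- exp(init$hyperparams$theta[["rho"]])
  s2 <- init$hyperparams$noise_var
  alpha <- rep(lam0, ss$D)
  trace <- numeric(0)
  init_rec <- list(noise_var = s2, alpha = lam0)
  tiny <- .Machine$double.xmin
  for (it in seq_len(maxit)) {
    v <- 1 / alpha
    prior <- ard_cov(log(alpha))
    res <- .ald_core(prior, ss, s2, need = "posterior",
                     prune_threshold = prune_threshold)
    trace <- c(trace, res$log_evidence)
    act <- res$active
    gam <- numeric(ss$D)
    gam[act] <- 1 - alpha[act] * res$cov_diag[act]
    mu2 <- res$mean^2
    alpha_new <- ifelse(act & mu2 > tiny, pmax(gam, 0) / pmax(mu2, tiny), Inf)
    alpha_new[!is.finite(alpha_new) | alpha_new <= 0] <- Inf
    s2_new <- res$rss / max(ss$n - sum(gam), 1e-8)
    if (!is.finite(s2_new) || s2_new <= 0) {
      stop("ARD fixed-point diverged (sigma^2 = ", format(s2_new), ")")
    }
    both <- is.finite(alpha) & is.finite(alpha_new)
    done <- (!any(both) ||
               max(abs(log(alpha_new[both]) - log(alpha[both]))) <
                 tol * max(1, max(abs(log(alpha[both]))))) &&
      abs(s2_new - s2) < tol * abs(s2)
    alpha <- alpha_new
    s2 <- s2_new
    if (done) break
  }
  prior <- ard_cov(log(alpha))
  post <- posterior_moments(ss, prior, s2, cov = FALSE,
                            prune_threshold = prune_threshold)
  .fit_result("ard", stats::setNames(log(alpha), paste0("rho", seq_len(ss$D))),
              s2, post, trace, init_rec, D = ss$D)
}

#' Default hyperparameter bounds
#'
#' Box constraints used for evidence optimization and as the support of
#' the uniform hyperprior in fully Bayesian inference. Chosen to be far
#' larger than the range of probable values: `rho` in \[-20, 20\], region
#' centers within \[-m_a, 2 m_a\] (spacetime) or \[0, m_a\] (frequency
#' magnitudes), Psi diagonal entries in \[1e-4, (4 m_a)^2\] with
#' off-diagonals bounded by the same magnitude (feasibility is enforced
#' separately), ASD length scales in \[0.05, 4 m_a\], and the noise
#' variance in \[1e-8, 10\] times `var(y)`.
#'
#' @param family family tag.
#' @param grid an [filter_grid()] object.
#' @param vy response variance (`yty / n`).
#' @return list with numeric vectors `lower` and `upper` over
#'   `(theta, noise_var)`.
#' @export
default_bounds <- function(family, grid, vy) {
  d <- grid$d
  m <- grid$shape
  psi_bounds <- function() {
    lo <- numeric(0); hi <- numeric(0)
    for (i in seq_len(d)) for (j in i:d) {
      cap <- (4 * sqrt(m[i] * m[j]))^2
      if (i == j) { lo <- c(lo, 1e-4); hi <- c(hi, cap) }
      else { lo <- c(lo, -cap); hi <- c(hi, cap) }
    }
    list(lo = lo, hi = hi)
  }
  pb <- if (d > 0) psi_bounds()
  blk <- switch(family,
    ridge = list(lo = -20, hi = 20),
    asd = list(lo = c(-20, rep(0.05, d)), hi = c(20, 4 * m)),
    alds = list(lo = c(-20, -m, pb$lo), hi = c(20, 2 * m, pb$hi)),
    aldf = list(lo = c(-20, rep(0, d), pb$lo), hi = c(20, m, pb$hi)),
    aldsf = {
      s <- list(lo = c(-20, -m, pb$lo), hi = c(20, 2 * m, pb$hi))
      f <- list(lo = c(-20, rep(0, d), pb$lo), hi = c(20, m, pb$hi))
      list(lo = c(s$lo, f$lo), hi = c(s$hi, f$hi))
    },
    stop("no default bounds for family '", family, "'")
  )
  nm <- theta_names(family, d = d)
  list(lower = stats::setNames(c(blk$lo, 1e-8 * vy), c(nm, "noise_var")),
       upper = stats::setNames(c(blk$hi, 10 * vy), c(nm, "noise_var")))
}

# smooth infeasibility penalty for non-PD Psi proposals: pushes L-BFGS-B
# back toward the PD cone along the min-eigenvalue direction
.psi_violation <- function(family, theta, d) {
  get_psis <- switch(family,
    alds = , aldf = list(theta[-(seq_len(1 + d))]),
    aldsf = {
      b <- .split_aldsf_theta(theta, d)
      list(b$s[-(seq_len(1 + d))], b$f[-(seq_len(1 + d))])
    },
    list()
  )
  viol <- 0
  grad <- numeric(length(theta))
  offset <- switch(family, alds = , aldf = 1 + d,
                   aldsf = 1 + d, 0)
  npsi <- d * (d + 1) / 2
  for (bi in seq_along(get_psis)) {
    entries <- get_psis[[bi]]
    M <- matrix(0, d, d)
    k <- 1L
    for (i in seq_len(d)) for (j in i:d) {
      M[i, j] <- M[j, i] <- entries[k]; k <- k + 1L
    }
    eg <- eigen(M, symmetric = TRUE)
    lmin <- eg$values[d]
    if (lmin < 1e-6) {
      viol <- viol + (1e-6 - lmin)
      v <- eg$vectors[, d]
      k <- 1L
      base <- offset + (bi - 1) * (1 + d + npsi)
      for (i in seq_len(d)) for (j in i:d) {
        g <- if (i == j) v[i]^2 else 2 * v[i] * v[j]
        grad[base + k] <- grad[base + k] - g  # d(-lmin)/dc
        k <- k + 1L
      }
    }
  }
  list(violation = viol, grad = grad)
}

#' Evidence optimization for ASD and the ALD families
#'
#' Bound-constrained quasi-Newton (L-BFGS-B) maximization of the log
#' evidence over `(theta, sigma^2)` using the analytic gradient. Proposals
#' with an infeasible (non-positive-definite) Psi are given a smooth
#' eigenvalue penalty that steers the optimizer back into the feasible
#' cone; the best feasible point encountered is returned, so the result is
#' never worse than the initialization.
#'
#' @param ss an [sufficient_stats()] object.
#' @param grid an [filter_grid()] object.
#' @param family one of `"asd"`, `"alds"`, `"aldf"`, `"aldsf"`.
#' @param init an [hyperparams()] object; computed by [initialize_ald()]
#'   when `NULL`.
#' @param bounds list with `lower`/`upper` over `(theta, noise_var)`;
#'   [default_bounds()] when `NULL`.
#' @param maxit L-BFGS-B iteration cap.
#' @param pgtol projected-gradient convergence tolerance.
#' @param prune_threshold relative prior-variance pruning threshold used
#'   during evidence evaluation.
#' @return An `ald_fit`.
#' @export
fit_evidence_opt <- function(ss, grid, family = c("asd", "alds", "aldf",
                                                  "aldsf"),
                             init = NULL, bounds = NULL, maxit = 150,
                             pgtol = 1e-3, prune_threshold = 1e-10) {
  family <- match.arg(family)
  stopifnot(inherits(ss, "ald_suffstats"), inherits(grid, "ald_grid"))
  if (is.null(init)) init <- initialize_ald(ss, grid, family)
  if (is.null(bounds)) bounds <- default_bounds(family, grid, .response_var(ss))
  p <- length(init$theta) + 1L
  lower <- bounds$lower
  upper <- bounds$upper
  stopifnot(length(lower) == p, length(upper) == p)
  x0 <- pmin(pmax(c(init$theta, init$noise_var), lower), upper)
  if (!psi_ok(family, x0[-p], grid$d)) {
    stop("no feasible initialization: initial Psi is not positive definite")
  }

  best <- new.env(parent = emptyenv())
  best$value <- -Inf
  best$x <- x0
  trace <- new.env(parent = emptyenv())
  trace$v <- numeric(0)
  cache <- new.env(parent = emptyenv())

  eval_point <- function(x) {
    if (!is.null(cache$x) && identical(cache$x, x)) return(cache$res)
    theta <- x[-p]
    s2 <- max(x[p], lower[p])
    pen <- .psi_violation(family, theta, grid$d)
    if (pen$violation > 0) {
      res <- list(value = -(1e8 * (1 + pen$violation)),
                  grad = c(-1e8 * pen$grad, 0), feasible = FALSE)
    } else {
      hp <- hyperparams(family, theta, s2, d = grid$d)
      eg <- .evidence_grad(ss, hp, grid, prune_threshold = prune_threshold)
      res <- list(value = eg$log_evidence, grad = unname(eg$grad),
                  feasible = TRUE)
      trace$v <- c(trace$v, eg$log_evidence)
      if (eg$log_evidence > best$value) {
        best$value <- eg$log_evidence
        best$x <- x
      }
    }
    cache$x <- x
    cache$res <- res
    res
  }

  opt <- stats::optim(
    x0,
    fn = function(x) -eval_point(x)$value,
    gr = function(x) -eval_point(x)$grad,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = maxit, pgtol = pgtol)
  )
  xb <- best$x
  s2 <- max(xb[p], lower[p])
  hp <- hyperparams(family, xb[-p], s2, d = grid$d)
  prior <- build_prior(hp, grid)
  post <- posterior_moments(ss, prior, s2, cov = FALSE,
                            prune_threshold = prune_threshold)
  .fit_result(family, stats::setNames(xb[-p], theta_names(family, d = grid$d)),
              s2, post, trace$v,
              list(theta = init$theta, noise_var = init$noise_var),
              d = grid$d,
              extra = list(convergence = opt$convergence,
                           optim_message = opt$message))
}

# feasibility of the Psi blocks inside a theta vector
psi_ok <- function(family, theta, d) {
  .psi_violation(family, theta, d)$violation == 0
}

#' Initialization heuristics for the ALD families
#'
#' ALDs: noise variance from the ridge fit, region center at the center of
#' mass of the absolute ridge estimate, Psi from a coarse grid of diagonal
#' scales (off-diagonals zero), scored by evidence. ALDf: region center at
#' the centroid of the Fourier power of the ridge estimate, analogous
#' grid. ALDsf: concatenation of the individually fitted ALDs and ALDf
#' hyperparameters, followed by a short scale-offset line search. ASD:
#' ridge scale with unit smoothness.
#'
#' @param ss an [sufficient_stats()] object.
#' @param grid an [filter_grid()] object.
#' @param family target family.
#' @param ridge_fit optional precomputed ridge `ald_fit`.
#' @return An [hyperparams()] object; attribute `"record"` holds the
#'   candidate grid and chosen point.
#' @export
initialize_ald <- function(ss, grid, family = c("asd", "alds", "aldf",
                                                "aldsf"),
                           ridge_fit = NULL) {
  family <- match.arg(family)
  d <- grid$d
  if (is.null(ridge_fit)) ridge_fit <- fit_ridge_eb(ss)
  s2 <- ridge_fit$hyperparams$noise_var
  mu_r <- ridge_fit$estimate

  psi_entries_diag <- function(taus) {
    out <- numeric(0)
    for (i in seq_len(d)) for (j in i:d) {
      out <- c(out, if (i == j) taus[i]^2 else 0)
    }
    out
  }
  scales <- c(0.08, 0.2, 0.5, 1, 2.5) # coarse log-spaced widths, axis units

  score <- function(theta) {
    hp <- hyperparams(family, theta, s2, d = d)
    .ald_core(build_prior(hp, grid), ss, s2)$log_evidence
  }

  if (family == "asd") {
    rho <- ridge_fit$hyperparams$theta[["rho"]]
    theta <- c(rho, rep(1, d))
    rec <- list(chosen = theta, source = "ridge scale, unit smoothness")
    hp <- hyperparams("asd", theta, s2, d = d)
    attr(hp, "record") <- rec
    return(hp)
  }

  if (family %in% c("alds", "aldf")) {
    if (family == "alds") {
      wgt <- abs(mu_r)
      pts <- grid$coords
      span <- grid$shape
    } else {
      wgt <- to_frequency(mu_r, grid_basis(grid))^2
      pts <- abs(freq_coords(grid))
      span <- grid$shape / 2
    }
    tot <- sum(wgt)
    nu <- if (tot > 0) drop(crossprod(pts, wgt)) / tot else colMeans(pts)
    rho <- -log(max(max(mu_r^2), 1e-12))
    cand <- lapply(scales, function(sc) {
      c(rho, nu, psi_entries_diag(pmax(sc * span, 0.05)))
    })
    vals <- vapply(cand, score, numeric(1))
    pick <- which.max(vals)
    hp <- hyperparams(family, cand[[pick]], s2, d = d)
    attr(hp, "record") <- list(candidates = cand, evidence = vals,
                               chosen = pick)
    return(hp)
  }

  # aldsf: fit the two component families, concatenate, then line-search a
  # shared scale offset (the product of the two scale factors otherwise
  # over-shrinks the combined prior variance)
  fit_s <- fit_evidence_opt(ss, grid, "alds",
                            init = initialize_ald(ss, grid, "alds",
                                                  ridge_fit = ridge_fit))
  fit_f <- fit_evidence_opt(ss, grid, "aldf",
                            init = initialize_ald(ss, grid, "aldf",
                                                  ridge_fit = ridge_fit))
  th_s <- unname(fit_s$hyperparams$theta)
  th_f <- unname(fit_f$hyperparams$theta)
  s2 <- fit_s$hyperparams$noise_var
  offsets <- seq(-8, 4, by = 1)
  vals <- vapply(offsets, function(a) {
    th <- c(th_s, th_f)
    th[1] <- max(min(th_s[1] + a, 20), -20)
    score(th)
  }, numeric(1))
  pick <- which.max(vals)
  theta <- c(th_s, th_f)
  theta[1] <- max(min(th_s[1] + offsets[pick], 20), -20)
  hp <- hyperparams("aldsf", theta, s2, d = d)
  attr(hp, "record") <- list(alds = fit_s$hyperparams, aldf = fit_f$hyperparams,
                             offsets = offsets, evidence = vals,
                             chosen = pick)
  hp
}

#' Fit a receptive field with any of the supported estimators
#'
#' Umbrella interface: builds the sufficient statistics and grid and
#' dispatches to the requested estimator. `"ml"` returns the whitened
#' spike-triggered average.
#'
#' @param X design matrix (`n x D`) or an `ald_suffstats` object.
#' @param y response vector (ignored when `X` is already a suffstats
#'   object).
#' @param shape filter axis lengths (or an `ald_grid`).
#' @param family one of `"ml"`, `"ridge"`, `"ard"`, `"asd"`, `"alds"`,
#'   `"aldf"`, `"aldsf"`.
#' @param ... passed to the family-specific fitter.
#' @return An `ald_fit` (for `"ml"`, a minimal fit object whose `estimate`
#'   is the ML solution).
#' @export
ald_fit <- function(X, y = NULL, shape, family = c("ml", "ridge", "ard",
                                                   "asd", "alds", "aldf",
                                                   "aldsf"), ...) {
  family <- match.arg(family)
  ss <- if (inherits(X, "ald_suffstats")) X else sufficient_stats(X, y)
  grid <- if (inherits(shape, "ald_grid")) shape else filter_grid(shape)
  if (grid$D != ss$D) {
    stop("grid implies D = ", grid$D, " but design has ", ss$D, " columns")
  }
  switch(family,
    ml = {
      est <- ml_estimate(ss)
      structure(list(hyperparams = NULL,
                     posterior = NULL, trace = numeric(0),
                     init = NULL, estimate = est),
                class = "ald_fit")
    },
    ridge = fit_ridge_eb(ss, ...),
    ard = fit_ard_eb(ss, ...),
    fit_evidence_opt(ss, grid, family, ...)
  )
}
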