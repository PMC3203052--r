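# Evidence and posterior computations for the linear-Gaussian model with a
# zero-mean Gaussian prior w ~ N(0, C(theta)).
#
# All quantities are evaluated from the sufficient statistics in D-space
# through a factor S with C = S S'. With A = I + S' X'X S / sigma^2 (always
# well-conditioned, even when C is nearly singular):
#   posterior covariance  Lambda = S A^{-1} S'
#   posterior mean        mu     = S A^{-1} S' X'y / sigma^2
#   log evidence          log N(y; 0, X C X' + sigma^2 I)
#                                = -1/2 [ n log(2 pi sigma^2) + log det A
#                                         + (y'y - b' A^{-1} b / sigma^2) / sigma^2 ]
# with b = S' X'y. This is the Woodbury / left-division form: C is never
# inverted, and pruned (zero prior variance) directions are handled by
# restriction to the active set.

.chol_jitter <- function(A) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-10 * sum(diag(A)) / nrow(A)
    R <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (is.null(R)) stop("covariance factorization failed twice (with jitter)")
  }
  R
}

# closed-form limit when the prior has all its mass at zero
.core_all_pruned <- function(ss, noise_var, ntheta, need_grad) {
  out <- list(
    log_evidence = -0.5 * (ss$n * log(2 * pi * noise_var) +
                             ss$yty / noise_var),
    mean = numeric(ss$D), cov_diag = numeric(ss$D),
    active = rep(FALSE, ss$D), rss = ss$yty, tr_lambda_xtx = 0
  )
  if (need_grad) {
    out$grad <- c(numeric(ntheta),
                  0.5 * (ss$yty / noise_var^2 - ss$n / noise_var))
  }
  out
}

# Single computational core shared by every prior family. `need` is a
# character subset of c("posterior", "cov", "grad").
.ald_core <- function(prior, ss, noise_var, need = character(),
                      prune_threshold = 1e-10, factor_tol = NULL) {
  stopifnot(inherits(prior, "ald_prior"), inherits(ss, "ald_suffstats"))
  if (!is.finite(noise_var) || noise_var <= 0) {
    stop("noise_var must be positive")
  }
  need_post <- "posterior" %in% need || "cov" %in% need || "grad" %in% need
  need_cov <- "cov" %in% need
  need_grad <- "grad" %in% need
  ntheta <- length(prior$dtheta)
  s2 <- noise_var

  if (prior$form %in% c("diag", "freq_diag")) {
    in_freq <- prior$form == "freq_diag"
    ssd <- if (in_freq) .freq_suffstats(ss, prior$basis) else ss
    v <- prior$diag
    vmax <- max(v)
    if (vmax <= 0) {
      out <- .core_all_pruned(ssd, s2, ntheta, need_grad)
      if (in_freq) out$active <- rep(TRUE, ss$D)
      return(out)
    }
    act <- v > prune_threshold * vmax
    s <- sqrt(v[act])
    Xa <- ssd$xtx[act, act, drop = FALSE]
    ba <- ssd$xty[act]
    G <- Xa * tcrossprod(s)
    A <- G / s2
    diag(A) <- diag(A) + 1
    R <- .chol_jitter(A)
    u <- backsolve(R, s * ba, transpose = TRUE)
    logev <- -0.5 * (ssd$n * log(2 * pi * s2) + 2 * sum(log(diag(R))) +
                       (ssd$yty - sum(u^2) / s2) / s2)
    out <- list(log_evidence = logev,
                active = if (in_freq) rep(TRUE, ss$D) else {
                  a <- logical(ss$D); a[act] <- TRUE; a
                })
    if (!need_post) return(out)

    z <- backsolve(R, u)
    mu_act <- s * z / s2
    mu_native <- numeric(ss$D)
    mu_native[act] <- mu_act
    Ainv <- chol2inv(R)
    cov_act <- Ainv * tcrossprod(s)
    out$tr_lambda_xtx <- sum(Ainv * G)
    w <- drop(Xa %*% mu_act)
    out$rss <- ssd$yty - 2 * sum(mu_act * ba) + sum(mu_act * w)
    cd_native <- numeric(ss$D)
    cd_native[act] <- s^2 * diag(Ainv)
    if (in_freq) {
      B <- prior$basis$B
      Bact <- B[act, , drop = FALSE]
      out$mean <- drop(crossprod(Bact, mu_act))
      CB <- cov_act %*% Bact
      out$cov_diag <- colSums(Bact * CB)
      if (need_cov) out$cov <- crossprod(Bact, CB)
    } else {
      out$mean <- mu_native
      out$cov_diag <- cd_native
      if (need_cov) {
        cov_full <- matrix(0, ss$D, ss$D)
        cov_full[act, act] <- cov_act
        out$cov <- cov_full
      }
    }
    if (need_grad) {
      alpha_act <- (ba - w) / s2
      HA <- Xa %*% cov_act
      diagPa <- (diag(Xa) - rowSums(HA * Xa) / s2) / s2
      g <- vapply(prior$dtheta, function(dt) {
        dd <- dt$diag[act]
        0.5 * (sum(alpha_act^2 * dd) - sum(diagPa * dd))
      }, numeric(1))
      gs <- 0.5 * (out$rss / s2^2 - ssd$n / s2 + out$tr_lambda_xtx / s2^2)
      out$grad <- c(g, noise_var = gs)
    }
    return(out)
  }

  if (prior$form == "dense") {
    C <- prior$dense
    if (!is.null(prior$fac_V)) {
      lam <- prior$fac_lam
      V <- prior$fac_V
    } else {
      eg <- eigen(C, symmetric = TRUE)
      lam <- eg$values
      V <- eg$vectors
    }
    lmax <- max(lam)
    if (lmax <= 0) return(.core_all_pruned(ss, s2, ntheta, need_grad))
    tol <- if (is.null(factor_tol)) ss$D * .Machine$double.eps else factor_tol
    keep <- lam > tol * lmax
    S <- V[, keep, drop = FALSE] *
      rep(sqrt(lam[keep]), each = nrow(V))
    r <- ncol(S)
    H <- ss$xtx %*% S
    G <- crossprod(S, H)
    A <- G / s2
    diag(A) <- diag(A) + 1
    R <- .chol_jitter(A)
    b_in <- drop(crossprod(S, ss$xty))
    u <- backsolve(R, b_in, transpose = TRUE)
    logev <- -0.5 * (ss$n * log(2 * pi * s2) + 2 * sum(log(diag(R))) +
                       (ss$yty - sum(u^2) / s2) / s2)
    out <- list(log_evidence = logev, active = rep(TRUE, ss$D))
    if (!need_post) return(out)
    z <- backsolve(R, u)
    mu <- drop(S %*% z) / s2
    Ainv <- chol2inv(R)
    out$tr_lambda_xtx <- sum(Ainv * G)
    xtxmu <- drop(H %*% z) / s2
    out$rss <- ss$yty - 2 * sum(mu * ss$xty) + sum(mu * xtxmu)
    SA <- S %*% Ainv
    out$cov_diag <- rowSums(SA * S)
    out$mean <- mu
    if (need_cov) out$cov <- tcrossprod(SA, S)
    if (need_grad) {
      alpha <- (ss$xty - xtxmu) / s2
      g <- vapply(prior$dtheta, function(dt) {
        dC <- dt$dense
        q1 <- sum(alpha * drop(dC %*% alpha))
        HdH <- crossprod(H, dC %*% H)
        tr_p <- (sum(ss$xtx * dC) - sum(Ainv * HdH) / s2) / s2
        0.5 * (q1 - tr_p)
      }, numeric(1))
      gs <- 0.5 * (out$rss / s2^2 - ss$n / s2 + out$tr_lambda_xtx / s2^2)
      out$grad <- c(g, noise_var = gs)
    }
    return(out)
  }

  if (prior$form == "sandwich") {
    ms <- prior$ms
    cf <- prior$cf
    if (max(ms) <= 0 || max(cf) <= 0) {
      return(.core_all_pruned(ss, s2, ntheta, need_grad))
    }
    as_ <- ms^2 > prune_threshold * max(ms^2)
    af <- cf > prune_threshold * max(cf)
    B <- prior$basis$B
    Bsub <- B[af, as_, drop = FALSE]
    msa <- ms[as_]
    cfa <- cf[af]
    S <- (msa * t(Bsub)) * rep(sqrt(cfa), each = sum(as_))
    Xa <- ss$xtx[as_, as_, drop = FALSE]
    ba <- ss$xty[as_]
    H <- Xa %*% S
    G <- crossprod(S, H)
    A <- G / s2
    diag(A) <- diag(A) + 1
    R <- .chol_jitter(A)
    b_in <- drop(crossprod(S, ba))
    u <- backsolve(R, b_in, transpose = TRUE)
    logev <- -0.5 * (ss$n * log(2 * pi * s2) + 2 * sum(log(diag(R))) +
                       (ss$yty - sum(u^2) / s2) / s2)
    act_full <- logical(ss$D)
    act_full[as_] <- TRUE
    out <- list(log_evidence = logev, active = act_full,
                active_freq = af)
    if (!need_post) return(out)
    z <- backsolve(R, u)
    mu_a <- drop(S %*% z) / s2
    mu <- numeric(ss$D)
    mu[as_] <- mu_a
    Ainv <- chol2inv(R)
    out$tr_lambda_xtx <- sum(Ainv * G)
    xamu <- drop(H %*% z) / s2
    out$rss <- ss$yty - 2 * sum(mu_a * ba) + sum(mu_a * xamu)
    SA <- S %*% Ainv
    cd <- numeric(ss$D)
    cd[as_] <- rowSums(SA * S)
    out$mean <- mu
    out$cov_diag <- cd
    if (need_cov) {
      cov_full <- matrix(0, ss$D, ss$D)
      cov_full[as_, as_] <- tcrossprod(SA, S)
      out$cov <- cov_full
    }
    if (need_grad) {
      alpha_a <- (ba - xamu) / s2
      P_a <- (Xa - tcrossprod(H %*% Ainv, H) / s2) / s2
      Q_a <- crossprod(sqrt(cfa) * Bsub)      # (B' Cf B)[as, as]
      v1 <- drop(Q_a %*% (msa * alpha_a))
      msP <- msa * P_a                         # rows scaled by ms
      diagQmsP <- rowSums(Q_a * t(msP))
      wt <- drop(Bsub %*% (msa * alpha_a))
      Pm <- P_a * tcrossprod(msa)
      T3 <- Bsub %*% Pm
      diagBPmB <- rowSums(T3 * Bsub)
      g <- vapply(prior$dtheta, function(dt) {
        if (!is.null(dt$dms)) {
          dmsa <- dt$dms[as_]
          sum(dmsa * alpha_a * v1) - sum(dmsa * diagQmsP)
        } else {
          dcfa <- dt$dcf[af]
          0.5 * (sum(dcfa * wt^2) - sum(dcfa * diagBPmB))
        }
      }, numeric(1))
      gs <- 0.5 * (out$rss / s2^2 - ss$n / s2 + out$tr_lambda_xtx / s2^2)
      out$grad <- c(g, noise_var = gs)
    }
    return(out)
  }
  stop("unknown prior form: ", prior$form)
}

# accept a plain PSD matrix as a prior covariance handle
.as_prior <- function(C, D) {
  if (inherits(C, "ald_prior")) return(C)
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || nrow(C) != D) {
    stop("prior covariance must be ", D, " x ", D)
  }
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(sum(diag(C)), .Machine$double.eps)) {
    stop("prior covariance is not positive semi-definite")
  }
  .new_prior("custom", D, "dense", dense = (C + t(C)) / 2, dtheta = list())
}

#' Log marginal likelihood (evidence)
#'
#' Computes `log p(y | X, theta, sigma^2)`, the log density of
#' `N(y; 0, X C X' + sigma^2 I)`, evaluated in D-space from the sufficient
#' statistics using the Woodbury identity and triangular solves, so a
#' nearly singular prior covariance never has to be inverted. The result is
#' finite for any positive semi-definite `C`, including `C = 0`.
#'
#' @param ss an [sufficient_stats()] object.
#' @param C prior covariance: an `ald_prior` or a plain `D x D` PSD matrix.
#' @param noise_var positive noise variance sigma^2.
#' @param prune_threshold relative prior-variance threshold below which
#'   coefficients are treated as pinned to zero.
#' @return scalar log evidence.
#' @export
log_evidence <- function(ss, C, noise_var, prune_threshold = 1e-10) {
  prior <- .as_prior(C, ss$D)
  .ald_core(prior, ss, noise_var, need = character(),
            prune_threshold = prune_threshold)$log_evidence
}

#' Gaussian posterior over the filter
#'
#' Posterior mean and covariance of the receptive field given the prior
#' covariance and noise variance. On the active set,
#' `Lambda = (X'X / sigma^2 + C^{-1})^{-1}` and
#' `mu = Lambda X'y / sigma^2`, computed in factored form (see
#' [log_evidence()]); coefficients whose prior variance is pruned to zero
#' get posterior mean 0 and zero covariance rows.
#'
#' @inheritParams log_evidence
#' @param cov if `TRUE` return the full posterior covariance; otherwise
#'   only its diagonal (the full `D x D` matrix can be large).
#' @return An object of class `ald_posterior`: `mean`, `cov` (or `NULL`),
#'   `cov_diag`, `active`, `log_evidence`.
#' @export
posterior_moments <- function(ss, C, noise_var, cov = TRUE,
                              prune_threshold = 1e-10) {
  prior <- .as_prior(C, ss$D)
  res <- .ald_core(prior, ss, noise_var,
                   need = if (cov) c("posterior", "cov") else "posterior",
                   prune_threshold = prune_threshold)
  structure(list(mean = res$mean, cov = res$cov, cov_diag = res$cov_diag,
                 active = res$active, log_evidence = res$log_evidence,
                 noise_var = noise_var),
            class = "ald_posterior")
}

#' @export
print.ald_posterior <- function(x, ...) {
  cat("<ald_posterior> D =", length(x$mean),
      " active =", sum(x$active),
      " log evidence =", format(x$log_evidence), "\n")
  invisible(x)
}

# analytic gradient of the log evidence over (theta, noise_var) at hp
.evidence_grad <- function(ss, hp, grid, prune_threshold = 1e-10) {
  prior <- build_prior(hp, grid)
  if (length(prior$dtheta) == 0L) {
    stop("family '", hp$family, "' has no registered dC/dtheta derivatives")
  }
  res <- .ald_core(prior, ss, hp$noise_var, need = "grad",
                   prune_threshold = prune_threshold)
  g <- res$grad
  names(g) <- c(names(prior$dtheta), "noise_var")
  list(grad = g, log_evidence = res$log_evidence)
}

#' Gradient and Hessian of the log evidence
#'
#' The gradient with respect to every hyperparameter and the noise
#' variance is assembled analytically by the chain rule through
#' `dC/dtheta_j`. The Hessian is obtained by central differencing of the
#' analytic gradient (step `step` per coordinate) and symmetrized; it is
#' used for the Metropolis-Hastings proposal scale.
#'
#' @param ss an [sufficient_stats()] object.
#' @param hp an [hyperparams()] object (families with registered
#'   derivatives: ridge, ard, asd, alds, aldf, aldsf).
#' @param grid an [filter_grid()] object.
#' @param hessian if `FALSE`, skip the Hessian.
#' @param step relative finite-difference step for the Hessian.
#' @return list with `gradient` (named, theta entries then `noise_var`),
#'   `hessian` (symmetric matrix, or `NULL`) and `log_evidence`.
#' @export
evidence_grad_hess <- function(ss, hp, grid, hessian = TRUE, step = 1e-5) {
  g0 <- .evidence_grad(ss, hp, grid)
  p <- length(g0$grad)
  H <- NULL
  if (hessian) {
    x0 <- c(hp$theta, hp$noise_var)
    H <- matrix(NA_real_, p, p)
    for (j in seq_len(p)) {
      h <- step * max(1, abs(x0[j]))
      gp <- gm <- NULL
      for (sgn in c(1, -1)) {
        x <- x0
        x[j] <- x[j] + sgn * h
        nv <- x[p]
        if (j == p && nv <= 0) nv <- x0[p] # one-sided fallback at the boundary
        hpj <- hyperparams(hp$family, x[-p], max(nv, 1e-12))
        gj <- tryCatch(.evidence_grad(ss, hpj, grid)$grad,
                       error = function(e) NULL)
        if (sgn > 0) gp <- gj else gm <- gj
      }
      if (is.null(gp) || is.null(gm)) {
        H[j, ] <- H[, j] <- NA_real_
      } else {
        H[j, ] <- (gp - gm) / (2 * h)
      }
    }
    H <- (H + t(H)) / 2
    dimnames(H) <- list(names(g0$grad), names(g0$grad))
  }
  list(gradient = g0$grad, hessian = H, log_evidence = g0$log_evidence)
}
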