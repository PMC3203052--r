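# Fully Bayesian inference: random-walk Metropolis-Hastings over the
# hyperparameters (and noise variance) with the evidence as unnormalized
# target and a uniform box hyperprior, plus a conditional Gaussian filter
# draw per state. One seeded generator drives proposals, acceptance draws
# and filter draws, in that order, so traces are exactly reproducible.

# draw one filter sample from the Gaussian posterior at (prior, sigma^2)
.draw_filter <- function(prior, ss, noise_var, prune_threshold = 1e-10) {
  res <- .ald_core(prior, ss, noise_var, need = "cov",
                   prune_threshold = prune_threshold)
  D <- length(res$mean)
  # factor the (possibly rank-deficient) posterior covariance
  eg <- eigen((res$cov + t(res$cov)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  z <- stats::rnorm(D)
  drop(res$mean + eg$vectors %*% (sqrt(lam) * z))
}

#' Metropolis-Hastings sampling of the hyperparameter posterior
#'
#' Random-walk MH on `(theta, sigma^2)` with an isotropic Gaussian
#' proposal whose variance is the largest eigenvalue of the inverse
#' negative Hessian of the log evidence at the mode. The target is
#' proportional to the evidence times a uniform hyperprior over the
#' bound-constraint box; proposals outside the box are rejected. One
#' filter draw from the conditional Gaussian posterior is recorded per
#' state (accepted or repeated).
#'
#' @param ss an [sufficient_stats()] object.
#' @param grid an [filter_grid()] object.
#' @param family prior family.
#' @param mode an [hyperparams()] object at the evidence maximizer (from
#'   the fit module).
#' @param support list with `lower`/`upper` over `(theta, noise_var)`;
#'   [default_bounds()] when `NULL`.
#' @param n_samples chain length T.
#' @param seed integer seed (reproducible traces).
#' @param proposal_scale optional fixed proposal standard deviation;
#'   overrides the Hessian-based choice. Also the fallback (with a
#'   warning) when the negative Hessian at the mode is not positive
#'   definite.
#' @param sample_noise_var if `FALSE`, keep sigma^2 fixed at the mode and
#'   sample theta only.
#' @param prune_threshold passed to the evidence evaluations.
#' @return An object of class `ald_mcmc`: `states` (T x p matrix),
#'   `accepted` (logical), `filter_draws` (T x D), `log_target`,
#'   `proposal_scale`, `seed`, `support`.
#' @export
mh_hyperposterior <- function(ss, grid, family, mode, support = NULL,
                              n_samples = 1000, seed = 1,
                              proposal_scale = NULL,
                              sample_noise_var = TRUE,
                              prune_threshold = 1e-10) {
  stopifnot(inherits(mode, "ald_hyperparams"), n_samples >= 1)
  family <- match.arg(family, .ald_families)
  d <- grid$d
  if (is.null(support)) {
    support <- default_bounds(family, grid, .response_var(ss))
  }
  p_theta <- length(mode$theta)
  p <- p_theta + 1L
  lower <- unname(support$lower)
  upper <- unname(support$upper)
  stopifnot(length(lower) == p, length(upper) == p)

  logev <- function(x) {
    theta <- x[-p]
    if (!psi_ok(family, theta, d)) return(-Inf)
    hp <- hyperparams(family, theta, x[p], d = d)
    .ald_core(build_prior(hp, grid), ss, x[p],
              prune_threshold = prune_threshold)$log_evidence
  }

  sigma_prop <- proposal_scale
  if (is.null(sigma_prop)) {
    gh <- evidence_grad_hess(ss, mode, grid, hessian = TRUE)
    H <- gh$hessian
    idx <- if (sample_noise_var) seq_len(p) else seq_len(p_theta)
    H <- H[idx, idx, drop = FALSE]
    ev <- tryCatch(eigen(-H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA_real_)
    if (anyNA(ev) || min(ev) <= 0) {
      warning("negative Hessian at the mode is not positive definite; ",
              "falling back to proposal scale 0.1")
      sigma_prop <- 0.1
    } else {
      # the log-evidence Hessian at the mode is negative definite; the
      # largest (least negative) eigenvalue of its inverse is -1 over the
      # strongest curvature, so the isotropic proposal is matched to the
      # stiffest direction and acceptance stays workable
      sigma_prop <- sqrt(1 / max(ev))
    }
  }

  set.seed(seed)
  x <- pmin(pmax(c(unname(mode$theta), mode$noise_var), lower), upper)
  lp <- logev(x)
  if (!is.finite(lp)) stop("mode is infeasible or outside the support")
  free <- if (sample_noise_var) seq_len(p) else seq_len(p_theta)
  states <- matrix(NA_real_, n_samples, p)
  draws <- matrix(NA_real_, n_samples, ss$D)
  accepted <- logical(n_samples)
  log_target <- numeric(n_samples)
  for (t in seq_len(n_samples)) {
    prop <- x
    prop[free] <- prop[free] + stats::rnorm(length(free), 0, sigma_prop)
    inside <- all(prop >= lower) && all(prop <= upper)
    lp_prop <- if (inside) logev(prop) else -Inf
    acc_draw <- stats::runif(1)
    if (is.finite(lp_prop) && acc_draw < exp(min(0, lp_prop - lp))) {
      x <- prop
      lp <- lp_prop
      accepted[t] <- TRUE
    }
    states[t, ] <- x
    log_target[t] <- lp
    hp_t <- hyperparams(family, x[-p], x[p], d = d)
    draws[t, ] <- .draw_filter(build_prior(hp_t, grid), ss, x[p],
                               prune_threshold = prune_threshold)
  }
  colnames(states) <- c(theta_names(family, d = d, D = ss$D), "noise_var")
  structure(list(states = states, accepted = accepted,
                 filter_draws = draws, log_target = log_target,
                 proposal_scale = sigma_prop, seed = seed,
                 family = family, support = support),
            class = "ald_mcmc")
}

#' @export
print.ald_mcmc <- function(x, ...) {
  cat("<ald_mcmc>", x$family, " T =", nrow(x$states),
      " acceptance =", format(mean(x$accepted), digits = 3),
      " proposal sd =", format(x$proposal_scale, digits = 3), "\n")
  invisible(x)
}

#' Fully Bayesian (Bayes least-squares) estimate and credible intervals
#'
#' Coordinatewise mean of the post-burn-in filter draws, with empirical
#' (interpolated) quantile intervals per coefficient.
#'
#' @param trace an [mh_hyperposterior()] result.
#' @param burn_in number of initial states to discard (default 10% of T).
#' @param level credible level (0.95 gives 2.5%/97.5% quantiles).
#' @return list with `mean` (D vector), `lower`, `upper` (D vectors),
#'   `level`, `n_draws`, and `warning_few_draws` (`TRUE` when fewer than
#'   100 post-burn-in draws were available).
#' @export
fb_estimate <- function(trace, burn_in = NULL, level = 0.95) {
  stopifnot(inherits(trace, "ald_mcmc"))
  T_ <- nrow(trace$filter_draws)
  if (is.null(burn_in)) burn_in <- floor(0.1 * T_)
  if (burn_in >= T_) stop("burn_in must be smaller than the chain length")
  keep <- trace$filter_draws[(burn_in + 1):T_, , drop = FALSE]
  few <- nrow(keep) < 100
  if (few) warning("fewer than 100 post-burn-in draws; summaries are noisy")
  a <- (1 - level) / 2
  qs <- apply(keep, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  list(mean = colMeans(keep), lower = qs[1L, ], upper = qs[2L, ],
       level = level, n_draws = nrow(keep), warning_few_draws = few)
}

#' Empirical-Bayes credible intervals
#'
#' Per-coefficient intervals `mu_i +/- z sqrt(Lambda_ii)` with `z` the
#' standard-normal quantile at `(1 + level) / 2`, conditioned on the
#' point-estimated hyperparameters.
#'
#' @param posterior an [posterior_moments()] object.
#' @param level credible level in (0, 1).
#' @return list with `lower`, `upper`, `level`.
#' @export
eb_credible_intervals <- function(posterior, level = 0.95) {
  stopifnot(inherits(posterior, "ald_posterior"), level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  hw <- z * sqrt(pmax(posterior$cov_diag, 0))
  list(lower = posterior$mean - hw, upper = posterior$mean + hw,
       level = level)
}
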