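# Simulated receptive fields, stimulus ensembles, responses and the error
# metrics used to benchmark the estimators.

#' Simulated receptive-field filters
#'
#' Generates ground-truth filters on a grid:
#' * `gabor` — Gaussian envelope times a cosine carrier (center, per-axis
#'   envelope widths, carrier frequency in cycles/pixel, orientation in
#'   radians for 2-D grids, phase); typical of a V1 simple cell.
#' * `dog` — amplitude-weighted difference of two concentric Gaussians
#'   (center-surround, typical of retinal ganglion cells).
#' * `grid_cell` — sum of three plane-wave cosines at 60 degree spacings
#'   under a broad Gaussian envelope (localized in frequency, not space).
#' * `windowed_noise` — seeded white noise inside a circular window
#'   (localized in space, not frequency).
#' * `white_noise` — seeded white noise (localized in neither basis).
#'
#' @param kind filter kind.
#' @param grid an [filter_grid()] object.
#' @param params named list of kind-specific parameters; unset entries get
#'   geometry-scaled defaults.
#' @param normalize if `TRUE` (default) scale the filter to unit L2 norm.
#' @return numeric vector of length `grid$D`.
#' @export
make_filter <- function(kind = c("gabor", "dog", "grid_cell",
                                 "windowed_noise", "white_noise"),
                        grid, params = list(), normalize = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "ald_grid"))
  ctr <- params$center %||% (grid$shape - 1) / 2
  X <- sweep(grid$coords, 2L, ctr)
  k <- switch(kind,
    gabor = {
      sd <- params$sd %||% (grid$shape / 4)
      freq <- params$freq %||% 0.25
      phase <- params$phase %||% 0
      theta <- params$orientation %||% (pi / 4)
      u <- if (grid$d == 2L) {
        X[, 1L] * cos(theta) + X[, 2L] * sin(theta)
      } else X[, 1L]
      env <- exp(-rowSums(sweep(X, 2L, sd, "/")^2) / 2)
      env * cos(2 * pi * freq * u + phase)
    },
    dog = {
      sd1 <- params$sd_center %||% (min(grid$shape) / 10)
      sd2 <- params$sd_surround %||% (2 * sd1)
      a1 <- params$amp_center %||% 1
      a2 <- params$amp_surround %||% (a1 * (sd1 / sd2)^grid$d)
      r2 <- rowSums(X^2)
      a1 * exp(-r2 / (2 * sd1^2)) - a2 * exp(-r2 / (2 * sd2^2))
    },
    grid_cell = {
      spacing <- params$spacing %||% (min(grid$shape) / 3)
      env_sd <- params$env_sd %||% (max(grid$shape) / 1.5)
      phase <- params$phase %||% 0
      angles <- (params$orientation %||% 0) + c(0, pi / 3, 2 * pi / 3)
      f <- 2 / (sqrt(3) * spacing)
      waves <- 0
      for (a in angles) {
        u <- if (grid$d >= 2L) {
          X[, 1L] * cos(a) + X[, 2L] * sin(a)
        } else X[, 1L] * cos(a)
        waves <- waves + cos(2 * pi * f * u + phase)
      }
      exp(-rowSums(X^2) / (2 * env_sd^2)) * waves
    },
    windowed_noise = {
      radius <- params$radius %||% (min(grid$shape) / 3)
      seed <- params$seed %||% 1L
      set.seed(seed)
      z <- stats::rnorm(grid$D)
      z * as.numeric(sqrt(rowSums(X^2)) <= radius)
    },
    white_noise = {
      seed <- params$seed %||% 1L
      set.seed(seed)
      stats::rnorm(grid$D)
    }
  )
  if (normalize) {
    nk <- sqrt(sum(k^2))
    if (nk == 0) stop("cannot normalize an all-zero filter")
    k <- k / nk
  }
  k
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stimulus ensembles
#'
#' Generates `n` stimulus samples on a grid:
#' * `white` — i.i.d. standard normal entries.
#' * `one_over_f` — correlated ("naturalistic") Gaussian noise with
#'   Fourier amplitude proportional to `1 / ||f||^(exponent/2)` (power
#'   `1 / ||f||^exponent`, default exponent 2); the DC amplitude is set to
#'   that of the lowest nonzero frequency, and samples are rescaled to
#'   unit marginal variance.
#' * `binary` — i.i.d. +/-1.
#'
#' @param kind stimulus kind.
#' @param n number of samples (rows).
#' @param grid an [filter_grid()] object.
#' @param seed integer seed.
#' @param exponent spectral power-decay exponent for `one_over_f`.
#' @return `n x D` numeric matrix.
#' @export
gen_stimuli <- function(kind = c("white", "one_over_f", "binary"), n, grid,
                        seed = 1, exponent = 2) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "ald_grid"), n >= 1)
  set.seed(seed)
  D <- grid$D
  if (kind == "white") {
    return(matrix(stats::rnorm(n * D), n, D))
  }
  if (kind == "binary") {
    return(matrix(sample(c(-1, 1), n * D, replace = TRUE), n, D))
  }
  basis <- grid_basis(grid)
  fmag <- sqrt(rowSums((basis$freq_coords /
                          rep(grid$shape, each = D))^2)) # cycles per pixel
  nz <- fmag > 0
  amp <- numeric(D)
  amp[nz] <- fmag[nz]^(-exponent / 2)
  amp[!nz] <- max(amp[nz]) # DC amplitude clamped to lowest nonzero frequency
  Z <- matrix(stats::rnorm(n * D), n, D)
  X <- (Z * rep(amp, each = n)) %*% basis$B # rows: B' (amp * z)
  X / sqrt(mean(amp^2))
}

#' Simulate responses from the linear-Gaussian model
#'
#' `y = X w + eps` with `eps ~ N(0, noise_var)` i.i.d.
#'
#' @param X design matrix.
#' @param w filter vector.
#' @param noise_var nonnegative noise variance.
#' @param seed integer seed.
#' @return numeric response vector.
#' @export
simulate_responses <- function(X, w, noise_var, seed = 1) {
  stopifnot(ncol(X) == length(w), noise_var >= 0)
  set.seed(seed)
  drop(X %*% w) + stats::rnorm(nrow(X), 0, sqrt(noise_var))
}

#' Normalized squared filter error
#'
#' `||k_hat - k_true||^2 / ||k_true||^2`. Equals 0 for a perfect estimate
#' and 1 for the all-zero estimate.
#'
#' @param k_true,k_hat numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
filter_error <- function(k_true, k_hat) {
  stopifnot(length(k_true) == length(k_hat))
  denom <- sum(k_true^2)
  if (denom == 0) stop("true filter must be nonzero")
  sum((k_hat - k_true)^2) / denom
}

#' Relative cross-validation error
#'
#' Test-set mean squared prediction error of an estimate minus the error
#' of the ML estimate trained on the test set itself, which lower-bounds
#' the test error of any linear predictor:
#' `(1/n) ||y - X w_hat||^2 - (1/n) ||y - X w_ML,test||^2 >= 0`.
#'
#' @param w_hat filter estimate (trained elsewhere).
#' @param X_test,y_test held-out design and response.
#' @return nonnegative scalar.
#' @export
relative_cv_error <- function(w_hat, X_test, y_test) {
  ss <- sufficient_stats(X_test, y_test)
  w_ml <- ml_estimate(ss)
  n <- nrow(X_test)
  e_hat <- sum((y_test - drop(X_test %*% w_hat))^2) / n
  e_ml <- sum((y_test - drop(X_test %*% w_ml))^2) / n
  max(e_hat - e_ml, 0)
}

#' Geometric-mean error ratios versus a reference method
#'
#' For a table of per-dataset errors (rows = datasets, columns = methods),
#' computes `exp(mean(log(e_method / e_ref)))` per method.
#'
#' @param errors numeric matrix or data frame of positive errors with
#'   named columns.
#' @param ref reference method (column name).
#' @return named numeric vector of geometric-mean ratios (reference = 1).
#' @export
error_ratio_summary <- function(errors, ref) {
  errors <- as.matrix(errors)
  if (any(!is.finite(errors)) || any(errors <= 0)) {
    stop("all errors must be positive and finite")
  }
  stopifnot(ref %in% colnames(errors))
  apply(errors, 2L, function(e) exp(mean(log(e / errors[, ref]))))
}

#' Non-overlapping block subsample of time indices
#'
#' Draws a training subset of exactly `size` samples as randomly chosen
#' non-overlapping blocks of `block` consecutive indices (without
#' replacement), emulating block resampling of a recording.
#'
#' @param n total number of samples.
#' @param size requested subset size (a multiple of `block` is used
#'   exactly; otherwise the final partial block is truncated to hit
#'   `size`).
#' @param block block length.
#' @param seed integer seed.
#' @return integer vector of `size` distinct indices.
#' @export
block_sample_indices <- function(n, size, block = 20L, seed = 1) {
  stopifnot(size <= n, size >= 1, block >= 1)
  set.seed(seed)
  n_blocks <- n %/% block
  need <- ceiling(size / block)
  if (need > n_blocks) stop("not enough blocks: need ", need, " of ", n_blocks)
  starts <- (sample(n_blocks, need) - 1L) * block + 1L
  idx <- unlist(lapply(starts, function(s) s:(s + block - 1L)))
  sort(idx)[seq_len(size)]
}

#' Simulate one benchmark dataset
#'
#' Convenience wrapper reproducing the simulation protocol used in the
#' package's benchmarks: a ground-truth filter, a stimulus ensemble, and
#' responses with unit signal variance (the filter is rescaled so that
#' `var(X w) = 1`) plus Gaussian noise.
#'
#' @param filter_kind,stim_kind see [make_filter()] and [gen_stimuli()].
#' @param n sample count.
#' @param grid an [filter_grid()] object.
#' @param noise_var noise variance (default 0.3 against signal variance 1).
#' @param seed integer seed (drives stimuli, responses, and any stochastic
#'   filter).
#' @param filter_params passed to [make_filter()].
#' @return list with `X`, `y`, `w` (the rescaled true filter), `grid`,
#'   `noise_var`, `seed`.
#' @export
simulate_scenario <- function(filter_kind, stim_kind, n, grid,
                              noise_var = 0.3, seed = 1,
                              filter_params = list()) {
  if (filter_kind %in% c("windowed_noise", "white_noise") &&
      is.null(filter_params$seed)) {
    filter_params$seed <- seed
  }
  w <- make_filter(filter_kind, grid, filter_params)
  X <- gen_stimuli(stim_kind, n, grid, seed = seed)
  sig <- stats::sd(drop(X %*% w))
  if (sig > 0) w <- w / sig
  y <- simulate_responses(X, w, noise_var, seed = seed + 1L)
  list(X = X, y = y, w = w, grid = grid, noise_var = noise_var, seed = seed)
}

#' Benchmark estimators over simulated datasets
#'
#' Runs a list of estimators over a grid of training sizes and seeds on a
#' fixed simulation scenario and returns a tidy table of normalized filter
#' errors.
#'
#' @param methods character vector of estimator names (see [ald_fit()]).
#' @param ns integer vector of training sizes.
#' @param seeds integer vector of seeds (one dataset per (n, seed) pair).
#' @param grid an [filter_grid()] object.
#' @param filter_kind,stim_kind,noise_var,filter_params scenario settings
#'   (see [simulate_scenario()]).
#' @return data frame with columns `method`, `n`, `seed`, `error`.
#' @export
benchmark_estimators <- function(methods, ns, seeds, grid,
                                 filter_kind = "gabor",
                                 stim_kind = "one_over_f",
                                 noise_var = 0.3,
                                 filter_params = list()) {
  rows <- list()
  for (n in ns) for (sd_ in seeds) {
    sc <- simulate_scenario(filter_kind, stim_kind, n, grid,
                            noise_var = noise_var, seed = sd_,
                            filter_params = filter_params)
    ss <- sufficient_stats(sc$X, sc$y)
    for (m in methods) {
      fit <- ald_fit(ss, shape = grid, family = m)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, n = n, seed = sd_,
        error = filter_error(sc$w, fit$estimate)
      )
    }
  }
  do.call(rbind, rows)
}
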