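# Prior covariance families for the hierarchical receptive-field model.
#
# Every family builds a zero-mean Gaussian prior covariance C(theta) over
# the D filter coefficients, together with the analytic derivative of C
# with respect to each hyperparameter. Scale hyperparameters enter as
# exp(-rho) (a log precision), so the optimizer is unconstrained in sign.
# Storage forms:
#   diag      — diagonal variances in the pixel basis (ridge, ARD, ALDs)
#   freq_diag — diagonal variances in the orthogonal Fourier basis (ALDf)
#   dense     — full D x D matrix (ASD, user-supplied covariances)
#   sandwich  — C = Ms B' Cf B Ms with Ms the elementwise square root of
#               the ALDs diagonal, Cf the ALDf diagonal and B the real
#               orthogonal DFT basis (ALDsf)
# Derivative structures mirror the storage form: a diagonal vector per
# hyperparameter, a dense matrix, or a (dms, dcf) pair for the sandwich.

.ald_families <- c("ridge", "ard", "asd", "alds", "aldf", "aldsf")

.new_prior <- function(family, D, form, ...) {
  structure(c(list(family = family, D = D, form = form), list(...)),
            class = "ald_prior")
}

#' @export
print.ald_prior <- function(x, ...) {
  cat("<ald_prior>", x$family, "(", x$form, ") D =", x$D, "\n")
  invisible(x)
}

#' Hyperparameter container
#'
#' Bundles a prior-family tag, its hyperparameter vector `theta` (ordering
#' documented in [theta_names()]) and the observation-noise variance, which
#' is treated as an extra hyperparameter and optimized jointly with `theta`.
#'
#' @param family one of `"ridge"`, `"ard"`, `"asd"`, `"alds"`, `"aldf"`,
#'   `"aldsf"`.
#' @param theta named or unnamed numeric vector, family-specific length.
#' @param noise_var positive noise variance sigma^2.
#' @param d coordinate dimensionality (needed to validate theta length for
#'   the geometric families); optional for ridge/ard.
#' @param D parameter dimensionality (needed for ard).
#' @return An object of class `ald_hyperparams`.
#' @export
hyperparams <- function(family, theta, noise_var, d = NULL, D = NULL) {
  family <- match.arg(family, .ald_families)
  if (noise_var <= 0) stop("noise_var must be positive")
  theta <- as.numeric(theta)
  if (family == "ard" && is.null(D)) D <- length(theta)
  if (!is.null(d) || family %in% c("asd", "alds", "aldf", "aldsf")) {
    expected <- theta_length(family, d = d, D = D)
    if (!is.na(expected) && length(theta) != expected) {
      stop("theta has length ", length(theta), " but family '", family,
           "' with d = ", d, " expects ", expected)
    }
  }
  if (family %in% c("ridge", "ard") || !is.null(d)) {
    names(theta) <- theta_names(family, d = d, D = D)
  }
  structure(list(family = family, theta = theta,
                 noise_var = as.numeric(noise_var)),
            class = "ald_hyperparams")
}

#' Hyperparameter vector layout
#'
#' `theta_names()` documents the fixed ordering of each family's
#' hyperparameter vector; `theta_length()` gives its length. Psi matrices
#' are stored by their `d(d+1)/2` upper-triangle entries `c_ij` (i <= j),
#' enumerated row-wise: `(1,1), (1,2), ..., (1,d), (2,2), ...`.
#'
#' * `ridge`: `(rho)`
#' * `ard`: `(rho_1, ..., rho_D)`
#' * `asd`: `(rho, delta_1, ..., delta_d)`
#' * `alds`: `(rho, nu_1..nu_d, psi entries)`
#' * `aldf`: `(rho, nu_1..nu_d, psi entries)`
#' * `aldsf`: concatenation of the `alds` block then the `aldf` block
#'
#' @param family family tag.
#' @param d coordinate dimensionality.
#' @param D parameter dimensionality (ard only).
#' @return Character vector of names / integer length.
#' @export
theta_names <- function(family, d = NULL, D = NULL) {
  family <- match.arg(family, .ald_families)
  psi_names <- function(prefix) {
    out <- character(0)
    for (i in seq_len(d)) for (j in i:d) {
      out <- c(out, paste0(prefix, "_c", i, j))
    }
    out
  }
  switch(family,
    ridge = "rho",
    ard = paste0("rho", seq_len(D)),
    asd = c("rho", paste0("delta", seq_len(d))),
    alds = c("rho_s", paste0("nu_s", seq_len(d)), psi_names("psi_s")),
    aldf = c("rho_f", paste0("nu_f", seq_len(d)), psi_names("psi_f")),
    aldsf = c(theta_names("alds", d = d), theta_names("aldf", d = d))
  )
}

#' @rdname theta_names
#' @export
theta_length <- function(family, d = NULL, D = NULL) {
  family <- match.arg(family, .ald_families)
  npsi <- if (!is.null(d)) d * (d + 1) / 2 else NA_integer_
  switch(family,
    ridge = 1L,
    ard = if (is.null(D)) NA_integer_ else as.integer(D),
    asd = if (is.null(d)) NA_integer_ else 1L + d,
    alds = ,
    aldf = if (is.null(d)) NA_integer_ else as.integer(1L + d + npsi),
    aldsf = if (is.null(d)) NA_integer_ else as.integer(2L * (1L + d + npsi))
  )
}

# split an aldsf theta into its alds / aldf blocks
.split_aldsf_theta <- function(theta, d) {
  nb <- theta_length("alds", d = d)
  list(s = theta[seq_len(nb)], f = theta[nb + seq_len(nb)])
}

#' Symmetric positive-definite region matrix from its entries
#'
#' Builds the `d x d` Psi matrix that defines the shape and extent of a
#' local region (in spacetime or frequency coordinates) from its
#' `d(d+1)/2` upper-triangle entries. Positive-definiteness is checked by
#' Cholesky factorization; an infeasible realization raises a condition of
#' class `ald_infeasible` so optimizers can treat it as an infeasible
#' proposal rather than a crash.
#'
#' @param entries numeric vector of length `d(d+1)/2`, order `c_ij`
#'   (i <= j), row-wise.
#' @param d coordinate dimensionality.
#' @return An object of class `ald_psi` with fields `d`, `entries`,
#'   `matrix`, `inv` (the inverse, from the Cholesky factor).
#' @export
psi_from_entries <- function(entries, d) {
  entries <- as.numeric(entries)
  if (length(entries) != d * (d + 1) / 2) {
    stop("expected ", d * (d + 1) / 2, " entries for d = ", d)
  }
  M <- matrix(0, d, d)
  k <- 1L
  for (i in seq_len(d)) for (j in i:d) {
    M[i, j] <- entries[k]
    M[j, i] <- entries[k]
    k <- k + 1L
  }
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R) || any(diag(R) <= 0)) {
    stop(structure(
      class = c("ald_infeasible", "error", "condition"),
      list(message = "Psi entries do not define a positive-definite matrix",
           call = sys.call(-1))
    ))
  }
  structure(list(d = d, entries = entries, matrix = M, inv = chol2inv(R)),
            class = "ald_psi")
}

#' Is a Psi entry vector feasible?
#'
#' @param entries,d as in [psi_from_entries()].
#' @return `TRUE` if the entries decode to a positive-definite matrix.
#' @export
psi_feasible <- function(entries, d) {
  !inherits(tryCatch(psi_from_entries(entries, d),
                     error = function(e) e), "error")
}

#' Ridge (i.i.d. shrinkage) prior covariance
#'
#' Diagonal covariance with constant variance `exp(-rho)`; the classical
#' L2 / ridge-regression prior.
#'
#' @param rho scale hyperparameter (log precision).
#' @param D parameter dimensionality.
#' @return An `ald_prior` in diagonal form with derivative structures.
#' @export
ridge_cov <- function(rho, D) {
  v <- rep(exp(-rho), D)
  .new_prior("ridge", D, "diag", diag = v,
             dtheta = list(rho = list(diag = -v)))
}

#' Automatic relevance determination prior covariance
#'
#' Diagonal covariance with a distinct variance `exp(-rho_i)` per filter
#' coefficient; evidence optimization drives irrelevant coefficients'
#' variances to zero, making the MAP estimate sparse.
#'
#' @param rhos numeric vector of per-coefficient log precisions.
#' @return An `ald_prior` in diagonal form.
#' @export
ard_cov <- function(rhos) {
  v <- exp(-rhos)
  D <- length(v)
  dth <- lapply(seq_len(D), function(i) {
    dd <- numeric(D); dd[i] <- -v[i]; list(diag = dd)
  })
  names(dth) <- paste0("rho", seq_len(D))
  .new_prior("ard", D, "diag", diag = v, dtheta = dth)
}

#' Automatic smoothness determination prior covariance
#'
#' Dense Gaussian-kernel covariance
#' `C_ij = exp(-rho - sum_a Delta_ij,a^2 / (2 delta_a^2))`, where
#' `Delta_ij,a` is the pixel distance between coefficients i and j along
#' coordinate axis a. One smoothness scale per coordinate dimension.
#'
#' @param rho overall scale (log precision).
#' @param deltas positive smoothness length scales, one per axis.
#' @param grid an [filter_grid()] object.
#' @return An `ald_prior` in dense form.
#' @export
asd_cov <- function(rho, deltas, grid) {
  stopifnot(inherits(grid, "ald_grid"))
  if (length(deltas) != grid$d) stop("need one delta per coordinate axis")
  if (any(deltas <= 0)) stop("smoothness scales `deltas` must be positive")
  E <- matrix(0, grid$D, grid$D)
  D2 <- vector("list", grid$d)
  # the kernel is separable across axes: C = exp(-rho) kron_a K_a, so its
  # eigendecomposition is the Kronecker product of small per-axis ones
  V <- NULL
  lam <- 1
  for (a in seq_len(grid$d)) {
    xa <- 0:(grid$shape[a] - 1L)
    Da1 <- outer(xa, xa, "-")
    Ka <- exp(-Da1 * Da1 / (2 * deltas[a]^2))
    ega <- eigen(Ka, symmetric = TRUE)
    V <- if (is.null(V)) ega$vectors else kronecker(V, ega$vectors)
    lam <- kronecker(lam, ega$values)
    Da <- outer(grid$coords[, a], grid$coords[, a], "-")
    D2[[a]] <- Da * Da
    E <- E + D2[[a]] / (2 * deltas[a]^2)
  }
  C <- exp(-rho - E)
  dth <- c(list(rho = list(dense = -C)),
           lapply(seq_len(grid$d), function(a) {
             list(dense = C * D2[[a]] / deltas[a]^3)
           }))
  names(dth) <- c("rho", paste0("delta", seq_len(grid$d)))
  .new_prior("asd", grid$D, "dense", dense = C, dtheta = dth,
             fac_V = V, fac_lam = pmax(exp(-rho) * lam, 0))
}

# Gaussian-profile diagonal over arbitrary coordinates; shared by ALDs
# (pixel coords) and ALDf (|frequency| coords). Returns the variance
# vector and per-hyperparameter derivative vectors in theta order
# (rho, nu_1..nu_d, psi entries row-wise upper triangle).
.local_diag <- function(rho, nu, psi, pts) {
  d <- ncol(pts)
  Xc <- sweep(pts, 2L, nu)
  U <- Xc %*% psi$inv           # row i = Psi^{-1} (x_i - nu)
  q <- rowSums(U * Xc)
  v <- exp(-rho - q / 2)
  dth <- vector("list", 1L + d + d * (d + 1) / 2)
  dth[[1L]] <- list(diag = -v)
  for (a in seq_len(d)) dth[[1L + a]] <- list(diag = v * U[, a])
  k <- 1L + d
  for (i in seq_len(d)) for (j in i:d) {
    k <- k + 1L
    dth[[k]] <- if (i == j) list(diag = 0.5 * v * U[, i]^2)
                else list(diag = v * U[, i] * U[, j])
  }
  list(diag = v, dtheta = dth)
}

#' Spacetime-localized (ALDs) prior covariance
#'
#' Diagonal covariance whose variance profile is a Gaussian bump over the
#' filter's spacetime coordinates:
#' `C_ii = exp(-rho_s - (chi_i - nu_s)' Psi_s^{-1} (chi_i - nu_s) / 2)`.
#' Coefficients far (in Mahalanobis distance) from the region center
#' `nu_s` get vanishing prior variance and can be pruned. With a very
#' broad region (`Psi_s` large) the profile flattens and the prior reduces
#' to ridge regression.
#'
#' @param rho_s overall scale (log precision).
#' @param nu_s numeric vector of length `d`, region center in pixel
#'   coordinates.
#' @param psi_s an [psi_from_entries()] object (or entry vector).
#' @param grid an [filter_grid()] object.
#' @return An `ald_prior` in diagonal form.
#' @export
alds_cov <- function(rho_s, nu_s, psi_s, grid) {
  stopifnot(inherits(grid, "ald_grid"))
  if (!inherits(psi_s, "ald_psi")) psi_s <- psi_from_entries(psi_s, grid$d)
  loc <- .local_diag(rho_s, nu_s, psi_s, grid$coords)
  names(loc$dtheta) <- theta_names("alds", d = grid$d)
  .new_prior("alds", grid$D, "diag", diag = loc$diag, dtheta = loc$dtheta)
}

#' Frequency-localized (ALDf) prior covariance
#'
#' Diagonal covariance in the real orthogonal Fourier basis:
#' `C_ii = exp(-rho_f - (|omega_i| - nu_f)' Psi_f^{-1} (|omega_i| - nu_f) / 2)`,
#' where `|omega_i|` is the componentwise absolute value of the signed
#' frequency coordinate. The absolute value enforces reflection symmetry
#' through the origin, `C(omega) = C(-omega)`, as required of the Fourier
#' transform of a real filter.
#'
#' @param rho_f overall scale (log precision).
#' @param nu_f numeric vector of length `d`, region center in frequency
#'   magnitude coordinates (componentwise nonnegative).
#' @param psi_f an [psi_from_entries()] object (or entry vector).
#' @param grid an [filter_grid()] object.
#' @return An `ald_prior` in `freq_diag` form carrying the basis handle.
#' @export
aldf_cov <- function(rho_f, nu_f, psi_f, grid) {
  stopifnot(inherits(grid, "ald_grid"))
  if (any(nu_f < 0)) stop("nu_f must be componentwise nonnegative")
  if (!inherits(psi_f, "ald_psi")) psi_f <- psi_from_entries(psi_f, grid$d)
  basis <- grid_basis(grid)
  loc <- .local_diag(rho_f, nu_f, psi_f, abs(basis$freq_coords))
  names(loc$dtheta) <- theta_names("aldf", d = grid$d)
  .new_prior("aldf", grid$D, "freq_diag", diag = loc$diag,
             dtheta = loc$dtheta, basis = basis)
}

#' Jointly localized (ALDsf) sandwich prior covariance
#'
#' Imposes spacetime and frequency locality in series through the sandwich
#' covariance `C = Ms B' Cf B Ms`, with `Ms` the elementwise square root of
#' the ALDs diagonal (pixel domain), `Cf` the ALDf diagonal (frequency
#' domain) and `B` the real orthogonal DFT basis. The matrix is stored in
#' factored form and is symmetric positive semi-definite by construction.
#' When both regions are broad `Ms` and `Cf` approach scaled identities and
#' the prior reduces to ridge regression.
#'
#' @param theta_s alds hyperparameter block `(rho_s, nu_s, psi_s entries)`.
#' @param theta_f aldf hyperparameter block `(rho_f, nu_f, psi_f entries)`.
#' @param grid an [filter_grid()] object.
#' @return An `ald_prior` in sandwich form with fields `ms` (pixel-domain
#'   square-root diagonal), `cf` (frequency-domain diagonal), `basis`, and
#'   derivative structures `(dms, dcf)` per hyperparameter.
#' @export
aldsf_cov <- function(theta_s, theta_f, grid) {
  stopifnot(inherits(grid, "ald_grid"))
  d <- grid$d
  npsi <- d * (d + 1) / 2
  stopifnot(length(theta_s) == 1 + d + npsi, length(theta_f) == 1 + d + npsi)
  psi_s <- psi_from_entries(theta_s[1 + d + seq_len(npsi)], d)
  psi_f <- psi_from_entries(theta_f[1 + d + seq_len(npsi)], d)
  if (any(theta_f[1 + seq_len(d)] < 0)) {
    stop("nu_f must be componentwise nonnegative")
  }
  basis <- grid_basis(grid)
  s <- .local_diag(theta_s[1], theta_s[1 + seq_len(d)], psi_s, grid$coords)
  f <- .local_diag(theta_f[1], theta_f[1 + seq_len(d)], psi_f,
                   abs(basis$freq_coords))
  ms <- sqrt(s$diag)
  # d(ms)/dtheta = d(Cs_ii)/dtheta / (2 ms); Cs derivatives are all
  # proportional to Cs = ms^2, so the ratio stays finite as ms -> 0
  dth <- c(
    lapply(s$dtheta, function(g) {
      list(dms = ifelse(ms > 0, g$diag / (2 * ms), 0), dcf = NULL)
    }),
    lapply(f$dtheta, function(g) list(dms = NULL, dcf = g$diag))
  )
  names(dth) <- theta_names("aldsf", d = d)
  .new_prior("aldsf", grid$D, "sandwich", ms = ms, cf = f$diag,
             basis = basis, dtheta = dth)
}

#' Build the prior covariance for a hyperparameter set
#'
#' Dispatches to the registered family constructor; this is the single
#' entry point used by the evidence, fitting and sampling code.
#'
#' @param hp an [hyperparams()] object.
#' @param grid an [filter_grid()] object (ignored for ridge/ard).
#' @return An `ald_prior`.
#' @export
build_prior <- function(hp, grid = NULL) {
  stopifnot(inherits(hp, "ald_hyperparams"))
  th <- hp$theta
  switch(hp$family,
    ridge = ridge_cov(th[1L], if (is.null(grid)) stop("ridge needs grid or D")
                      else grid$D),
    ard = ard_cov(th),
    asd = asd_cov(th[1L], th[-1L], grid),
    alds = {
      d <- grid$d
      alds_cov(th[1L], th[1L + seq_len(d)], th[-(seq_len(1L + d))], grid)
    },
    aldf = {
      d <- grid$d
      aldf_cov(th[1L], th[1L + seq_len(d)], th[-(seq_len(1L + d))], grid)
    },
    aldsf = {
      blocks <- .split_aldsf_theta(th, grid$d)
      aldsf_cov(blocks$s, blocks$f, grid)
    }
  )
}

#' Densify a prior covariance
#'
#' Reconstructs the full `D x D` covariance matrix from any storage form.
#' Intended for inspection and testing; the estimation code works with the
#' factored forms.
#'
#' @param prior an `ald_prior`.
#' @return `D x D` symmetric matrix (pixel basis).
#' @export
prior_matrix <- function(prior) {
  stopifnot(inherits(prior, "ald_prior"))
  switch(prior$form,
    diag = diag(prior$diag, prior$D),
    freq_diag = {
      B <- prior$basis$B
      crossprod(B * sqrt(prior$diag)) # B' diag(v) B
    },
    dense = prior$dense,
    sandwich = {
      B <- prior$basis$B
      Q <- crossprod(B * sqrt(prior$cf)) # B' Cf B
      prior$ms * t(prior$ms * Q)         # Ms Q Ms
    }
  )
}

#' Active (unpruned) coefficients or factor directions of a prior
#'
#' Directions whose prior variance falls below `threshold` times the
#' maximum variance are deactivated; the prior pins them to zero, so the
#' posterior there is a delta at zero. For the sandwich family the pixel
#' and frequency diagonals are thresholded separately.
#'
#' @param prior an `ald_prior`.
#' @param threshold relative pruning threshold in (0, 1).
#' @return For diagonal/dense forms a logical vector of length `D`; for
#'   the sandwich form a list with logical vectors `space` and `freq`.
#' @export
prune_active <- function(prior, threshold = 1e-10) {
  stopifnot(inherits(prior, "ald_prior"), threshold > 0, threshold < 1)
  act <- switch(prior$form,
    diag = ,
    freq_diag = prior$diag > threshold * max(prior$diag),
    dense = diag(prior$dense) > threshold * max(diag(prior$dense)),
    sandwich = list(space = prior$ms^2 > threshold * max(prior$ms^2),
                    freq = prior$cf > threshold * max(prior$cf))
  )
  flat <- if (is.list(act)) unlist(act) else act
  if (!any(flat)) stop("degenerate prior: all coefficients pruned")
  act
}
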