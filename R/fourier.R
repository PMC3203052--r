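# Real orthogonal discrete-Fourier basis for d-dimensional filter grids.
#
# Rows are normalized cosine/sine pairs per frequency; the full basis for a
# multi-axis grid is the Kronecker (tensor) product across axes, matching
# the row-major coefficient enumeration of `filter_grid()`. Frequencies are
# indexed in cycles per axis, in the range -floor(m/2) .. ceiling(m/2)-1
# for an axis of length m; the cosine row of a pair carries +k and the sine
# row -k, so conjugate pairs are (+k, -k). The Nyquist row (even m) and the
# DC row are self-conjugate singletons.

.dft_basis_1d <- function(m) {
  t <- 0:(m - 1L)
  B <- matrix(0, m, m)
  freqs <- numeric(m)
  B[1L, ] <- 1 / sqrt(m)
  freqs[1L] <- 0
  row <- 2L
  kmax <- floor((m - 1L) / 2L)
  for (k in seq_len(kmax)) {
    B[row, ] <- sqrt(2 / m) * cos(2 * pi * k * t / m)
    freqs[row] <- k
    B[row + 1L, ] <- sqrt(2 / m) * sin(2 * pi * k * t / m)
    freqs[row + 1L] <- -k
    row <- row + 2L
  }
  if (m %% 2L == 0L && m > 1L) {
    B[row, ] <- cos(pi * t) / sqrt(m) # alternating +-1
    freqs[row] <- -m / 2
  }
  list(B = B, freqs = freqs)
}

#' Real orthogonal DFT basis
#'
#' Builds a real orthogonal basis `B` (`D x D`) for the d-dimensional
#' discrete Fourier transform over a filter grid, together with the signed
#' frequency coordinate of every basis row and the list of conjugate
#' `(omega, -omega)` row pairs. `B %*% w` maps a filter from the pixel
#' domain to the frequency domain; `t(B)` maps back.
#'
#' @param shape integer vector of axis lengths (1--3 axes).
#' @return An object of class `ald_basis`: `B` (orthogonal matrix),
#'   `freq_coords` (`D x d` signed frequencies, cycles per axis length),
#'   `conjugate_pairs` (2-column integer matrix of row pairs), `shape`.
#' @examples
#' b <- dft_basis(4)
#' max(abs(b$B %*% t(b$B) - diag(4))) # orthonormal
#' @export
dft_basis <- function(shape) {
  shape <- as.integer(shape)
  stopifnot(length(shape) >= 1L, all(shape >= 1L))
  parts <- lapply(shape, .dft_basis_1d)
  B <- parts[[1L]]$B
  fc <- matrix(parts[[1L]]$freqs, ncol = 1L)
  if (length(parts) > 1L) {
    for (a in 2L:length(parts)) {
      B <- kronecker(B, parts[[a]]$B)
      fc <- cbind(
        fc[rep(seq_len(nrow(fc)), each = shape[a]), , drop = FALSE],
        rep(parts[[a]]$freqs, times = nrow(fc))
      )
    }
  }
  # conjugate pairs: match each row's frequency vector with its negation,
  # aliasing the Nyquist label (+m/2 is stored as -m/2 on an even axis)
  negfc <- -fc
  for (a in seq_along(shape)) {
    hit <- negfc[, a] == shape[a] / 2
    negfc[hit, a] <- -shape[a] / 2
  }
  key <- apply(fc, 1L, paste, collapse = ",")
  negkey <- apply(negfc, 1L, paste, collapse = ",")
  partner <- match(negkey, key)
  sel <- which(seq_along(partner) < partner)
  pairs <- cbind(sel, partner[sel])
  structure(
    list(B = B, freq_coords = fc, conjugate_pairs = pairs, shape = shape),
    class = "ald_basis"
  )
}

#' Transform to and from the frequency domain
#'
#' `to_frequency()` applies the orthogonal DFT: a filter vector `w` maps to
#' `B %*% w`; a stimulus matrix (rows = samples) maps to `X %*% t(B)`, i.e.
#' every row is transformed. `from_frequency()` is the exact inverse.
#'
#' @param x numeric vector of length `D`, or matrix with `D` columns.
#' @param basis an [dft_basis()] object.
#' @return Transformed object of the same shape.
#' @export
to_frequency <- function(x, basis) {
  stopifnot(inherits(basis, "ald_basis"))
  D <- nrow(basis$B)
  if (is.matrix(x)) {
    if (ncol(x) != D) stop("trailing dimension must equal basis size ", D)
    x %*% t(basis$B)
  } else {
    if (length(x) != D) stop("vector length must equal basis size ", D)
    drop(basis$B %*% x)
  }
}

#' @rdname to_frequency
#' @export
from_frequency <- function(x, basis) {
  stopifnot(inherits(basis, "ald_basis"))
  D <- nrow(basis$B)
  if (is.matrix(x)) {
    if (ncol(x) != D) stop("trailing dimension must equal basis size ", D)
    x %*% basis$B
  } else {
    if (length(x) != D) stop("vector length must equal basis size ", D)
    drop(crossprod(basis$B, x))
  }
}
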