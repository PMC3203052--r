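#' Filter coordinate grid
#'
#' Describes the coordinate system of a receptive-field filter: its
#' coordinate dimensionality `d` (1--3), the per-axis lengths `shape`, the
#' parameter dimensionality `D = prod(shape)`, and the spacetime coordinates
#' of every filter coefficient.
#'
#' Coefficients are enumerated in row-major (C) order over `shape`: the last
#' axis varies fastest. Coordinates are 0-based pixel indices, so axis `a`
#' takes values `0 .. shape[a] - 1`. Frequency coordinates (in cycles per
#' axis length) are attached lazily via [dft_basis()] and follow the same
#' enumeration convention.
#'
#' @param shape integer vector of 1--3 positive axis lengths.
#' @return An object of class `ald_grid` with fields `d`, `shape`, `D`,
#'   `coords` (`D x d` matrix of pixel coordinates).
#' @examples
#' g <- filter_grid(c(2, 3))
#' g$coords # rows enumerate (0,0), (0,1), (0,2), (1,0), ...
#' @export
filter_grid <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) < 1L || length(shape) > 3L || any(shape < 1L) ||
      anyNA(shape)) {
    stop("`shape` must be 1-3 positive integer axis lengths")
  }
  d <- length(shape)
  D <- prod(shape)
  # strides for row-major order: last axis fastest
  strides <- rev(cumprod(rev(c(shape[-1L], 1L))))
  idx <- 0:(D - 1L)
  coords <- matrix(0, nrow = D, ncol = d)
  for (a in seq_len(d)) {
    coords[, a] <- (idx %/% strides[a]) %% shape[a]
  }
  structure(
    list(d = d, shape = shape, D = D, coords = coords,
         cache = new.env(parent = emptyenv())),
    class = "ald_grid"
  )
}

#' @export
print.ald_grid <- function(x, ...) {
  cat("<ald_grid> d =", x$d, " shape =", paste(x$shape, collapse = " x "),
      " D =", x$D, "\n")
  invisible(x)
}

#' Fourier basis attached to a grid (memoized)
#'
#' Returns the real orthogonal DFT basis for `grid$shape`, computing it on
#' first use and caching it on the grid object.
#'
#' @param grid an [filter_grid()] object.
#' @return An `ald_basis` object (see [dft_basis()]).
#' @export
grid_basis <- function(grid) {
  stopifnot(inherits(grid, "ald_grid"))
  if (is.null(grid$cache$basis)) {
    grid$cache$basis <- dft_basis(grid$shape)
  }
  grid$cache$basis
}

#' Frequency coordinates of a grid
#'
#' @param grid an [filter_grid()] object.
#' @return `D x d` matrix of signed frequency coordinates (cycles per axis
#'   length), row `i` matching row `i` of the Fourier basis.
#' @export
freq_coords <- function(grid) {
  grid_basis(grid)$freq_coords
}
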