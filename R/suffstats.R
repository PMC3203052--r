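#' Sufficient statistics of the linear-Gaussian encoding model
#'
#' All evidence and posterior computations in this package depend on the
#' data only through `X'X`, `X'y`, `y'y` and the sample count `n`, so the
#' cost of hyperparameter optimization does not scale with the amount of
#' data. Accumulation can be chunked for designs too large to hold the
#' Gram product in one pass.
#'
#' @param X numeric design matrix (`n x D`, rows = time bins / samples).
#' @param y numeric response vector of length `n` (spike counts or a
#'   continuous response).
#' @param chunk_size optional positive integer; accumulate `X'X` and `X'y`
#'   in row blocks of this size. The result equals the one-shot product.
#' @return An object of class `ald_suffstats` with fields `xtx`, `xty`,
#'   `yty`, `n`, `D`.
#' @export
sufficient_stats <- function(X, y, chunk_size = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop("dimension mismatch: X has ", nrow(X), " rows but y has ",
         length(y), " entries")
  }
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  n <- nrow(X)
  D <- ncol(X)
  if (is.null(chunk_size)) {
    xtx <- crossprod(X)
    xty <- drop(crossprod(X, y))
  } else {
    chunk_size <- as.integer(chunk_size)
    stopifnot(chunk_size >= 1L)
    xtx <- matrix(0, D, D)
    xty <- numeric(D)
    start <- 1L
    while (start <= n) {
      end <- min(start + chunk_size - 1L, n)
      Xi <- X[start:end, , drop = FALSE]
      xtx <- xtx + crossprod(Xi)
      xty <- xty + drop(crossprod(Xi, y[start:end]))
      start <- end + 1L
    }
  }
  suffstats(xtx, xty, sum(y^2), n)
}

#' Assemble sufficient statistics from precomputed pieces
#'
#' @param xtx `D x D` symmetric positive semi-definite Gram matrix.
#' @param xty numeric vector of length `D` (spike-triggered sum).
#' @param yty nonnegative scalar, sum of squared responses.
#' @param n positive integer sample count.
#' @return An `ald_suffstats` object.
#' @export
suffstats <- function(xtx, xty, yty, n) {
  xtx <- as.matrix(xtx)
  xty <- as.numeric(xty)
  if (nrow(xtx) != ncol(xtx) || nrow(xtx) != length(xty)) {
    stop("xtx must be square with one row per entry of xty")
  }
  if (yty < 0 || n < 1) stop("yty must be nonnegative and n >= 1")
  structure(
    list(xtx = xtx, xty = xty, yty = as.numeric(yty), n = as.integer(n),
         D = length(xty), cache = new.env(parent = emptyenv())),
    class = "ald_suffstats"
  )
}

#' @export
print.ald_suffstats <- function(x, ...) {
  cat("<ald_suffstats> D =", x$D, " n =", x$n, "\n")
  invisible(x)
}

# frequency-domain congruence of the sufficient statistics, memoized on the
# suffstats object (used by the ALDf estimator, which is diagonal in the
# Fourier basis)
.freq_suffstats <- function(ss, basis) {
  key <- paste0("freq_", paste(basis$shape, collapse = "x"))
  got <- ss$cache[[key]]
  if (!is.null(got)) return(got)
  B <- basis$B
  out <- suffstats(B %*% ss$xtx %*% t(B), drop(B %*% ss$xty), ss$yty, ss$n)
  ss$cache[[key]] <- out
  out
}

#' Maximum-likelihood (whitened STA) estimate
#'
#' Solves `X'X w = X'y` by a symmetric factorization; this is the
#' whitened spike-triggered average, the ML filter under the
#' linear-Gaussian model. The Gram matrix is never inverted explicitly.
#'
#' @param ss an [sufficient_stats()] object.
#' @param max_kappa condition-number cap; a Gram matrix with reciprocal
#'   condition below `1/max_kappa` raises a rank-deficiency error naming
#'   the number of deficient dimensions.
#' @return numeric vector of length `D`.
#' @export
ml_estimate <- function(ss, max_kappa = 1e12) {
  stopifnot(inherits(ss, "ald_suffstats"))
  rc <- tryCatch(rcond(ss$xtx), error = function(e) 0)
  if (!is.finite(rc) || rc < 1 / max_kappa) {
    rank <- qr(ss$xtx)$rank
    stop("rank-deficient Gram matrix: ", ss$D - rank,
         " deficient dimension(s) (rcond = ", signif(rc, 3), ")")
  }
  drop(solve(ss$xtx, ss$xty))
}
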