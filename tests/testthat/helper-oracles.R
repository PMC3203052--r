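# Independent oracles and fixture builders shared across tests.

# dense n-space Gaussian marginal: log N(y; 0, X C X' + sigma^2 I),
# computed directly in sample space (never through the package's D-space
# Woodbury path)
ev_oracle_nspace <- function(X, C, noise_var, y) {
  n <- nrow(X)
  K <- X %*% C %*% t(X) + diag(noise_var, n)
  R <- chol((K + t(K)) / 2)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) +
            sum(backsolve(R, y, transpose = TRUE)^2))
}

# dense brute-force posterior: (X'X/s2 + C^{-1})^{-1} with a tiny ridge on
# C so the explicit inverse exists
posterior_oracle_dense <- function(ss, C, noise_var) {
  D <- ss$D
  Lam <- solve(ss$xtx / noise_var + solve(C + diag(1e-13, D)))
  list(mean = drop(Lam %*% ss$xty) / noise_var, cov = Lam)
}

# small random regression instance
rand_instance <- function(n, D, seed, noise_sd = 0.8) {
  set.seed(seed)
  X <- matrix(rnorm(n * D), n, D)
  y <- rnorm(n, 0, noise_sd)
  list(X = X, y = y, ss = aldrf::sufficient_stats(X, y))
}

# moderate random hyperparameters for a family on a given grid
rand_theta <- function(family, grid, seed) {
  set.seed(seed)
  d <- grid$d
  psi_entries <- function() {
    out <- numeric(0)
    for (i in seq_len(d)) for (j in i:d) {
      out <- c(out, if (i == j) runif(1, 1, 9) else runif(1, -0.4, 0.4))
    }
    out
  }
  switch(family,
    ridge = rnorm(1, 0, 0.5),
    ard = rnorm(grid$D, 0, 0.5),
    asd = c(rnorm(1, 0, 0.5), runif(d, 0.8, 2.5)),
    alds = c(rnorm(1, 0, 0.5), (grid$shape - 1) / 2 + rnorm(d, 0, 0.5),
             psi_entries()),
    aldf = c(rnorm(1, 0, 0.5), runif(d, 0.5, 2), psi_entries()),
    aldsf = c(rand_theta("alds", grid, seed), rand_theta("aldf", grid,
                                                         seed + 1000))
  )
}

# central finite-difference gradient of f at x
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    hp <- x; hp[j] <- hp[j] + h
    hm <- x; hm[j] <- hm[j] - h
    (f(hp) - f(hm)) / (2 * h)
  }, numeric(1))
}

# 1-D difference-of-Gaussians test filter (smooth, localized)
dog_1d <- function(D = 100, center = (D - 1) / 2, s1 = 5, s2 = 10, a2 = 0.5) {
  x <- 0:(D - 1)
  w <- exp(-(x - center)^2 / (2 * s1^2)) - a2 * exp(-(x - center)^2 / (2 * s2^2))
  w / sqrt(sum(w^2))
}
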