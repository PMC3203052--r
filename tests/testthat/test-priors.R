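test_that("ridge and ARD covariances follow the log-precision convention", {
  expect_equal(ridge_cov(0, 3)$diag, rep(1, 3))
  expect_equal(ridge_cov(log(4), 2)$diag, rep(0.25, 2))
  expect_equal(ard_cov(c(0, log(2)))$diag, c(1, 0.5))
  # large rho drives the variance below any pruning threshold
  expect_lt(ard_cov(c(0, 50))$diag[2], 1e-20)
  # derivatives vs finite differences
  h <- 1e-6
  fd <- (ridge_cov(0.3 + h, 4)$diag - ridge_cov(0.3 - h, 4)$diag) / (2 * h)
  expect_equal(ridge_cov(0.3, 4)$dtheta$rho$diag, fd, tolerance = 1e-8)
  fd2 <- (ard_cov(c(0.3 + h, -1))$diag - ard_cov(c(0.3 - h, -1))$diag) / (2 * h)
  expect_equal(ard_cov(c(0.3, -1))$dtheta$rho1$diag, fd2, tolerance = 1e-8)
})

test_that("ASD kernel has the Gaussian fuzzy-ridge form", {
  g <- filter_grid(6L)
  C <- asd_cov(0.4, 2, g)$dense
  expect_equal(diag(C), rep(exp(-0.4), 6))
  expect_equal(C[1, 3], exp(-0.4 - 4 / 8)) # distance 2, delta 2
  # elementwise brute force
  for (i in 1:6) for (j in 1:6) {
    expect_equal(C[i, j], exp(-0.4 - (i - j)^2 / (2 * 4)), tolerance = 1e-12)
  }
  # vanishing length scale: effectively the ridge prior
  C0 <- asd_cov(0.4, 1e-4, g)$dense
  expect_lt(max(abs(C0 - diag(exp(-0.4), 6))), 1e-300)
  expect_error(asd_cov(0, c(-1), g), "positive")
  # 2-D anisotropic kernel separates across axes: coords (0,0) vs (1,3)
  g2 <- filter_grid(c(3, 4))
  C2 <- asd_cov(0, c(1, 3), g2)$dense
  expect_equal(C2[1, 8], exp(-1 / 2 - 9 / 18), tolerance = 1e-12)
})

test_that("Psi matrices decode, validate, and reject infeasible entries", {
  expect_equal(psi_from_entries(4, 1)$matrix, matrix(4))
  expect_equal(psi_from_entries(c(2, 0, 3), 2)$matrix,
               matrix(c(2, 0, 0, 3), 2))
  err <- tryCatch(psi_from_entries(c(1, 2, 1), 2), error = function(e) e)
  expect_s3_class(err, "ald_infeasible")
  expect_false(psi_feasible(c(1, 2, 1), 2))
  expect_true(psi_feasible(c(1, 0.5, 1), 2))
})

test_that("ALDs prior variance follows the Mahalanobis profile", {
  g <- filter_grid(8L)
  pr <- alds_cov(0.7, 3, 4, g)
  expect_equal(pr$diag[4], exp(-0.7)) # coordinate 3 == center
  # 2-D analytic point: chi = (2,0), nu = 0, Psi = I
  g2 <- filter_grid(c(5, 5))
  pr2 <- alds_cov(0, c(0, 0), c(1, 0, 1), g2)
  i <- which(g2$coords[, 1] == 2 & g2$coords[, 2] == 0)
  expect_equal(pr2$diag[i], exp(-2), tolerance = 1e-12)
  # broad-region limit reduces to ridge
  prb <- alds_cov(0.2, 3.5, 1e8, g) # tau = 1e4
  expect_lt(max(abs(prb$diag - exp(-0.2))), 1e-6)
})

test_that("ALDf prior is reflection-symmetric and analytic on-peak", {
  g <- filter_grid(12L)
  b <- grid_basis(g)
  pr <- aldf_cov(0.3, 2, 1.5, g)
  peak <- which(abs(b$freq_coords[, 1]) == 2)
  expect_equal(pr$diag[peak], rep(exp(-0.3), length(peak)))
  cp <- b$conjugate_pairs
  expect_equal(pr$diag[cp[, 1]], pr$diag[cp[, 2]]) # exact symmetry
  # 1-D analytic evaluation: rho = 0, nu = 3, Psi = 4, omega = 5
  pr2 <- aldf_cov(0, 3, 4, g)
  i5 <- which(b$freq_coords[, 1] == 5)
  expect_equal(pr2$diag[i5], exp(-0.5), tolerance = 1e-12)
  expect_error(aldf_cov(0, -1, 4, g), "nonnegative")
})

test_that("ALDsf sandwich reconstructs a PSD matrix and its factored
           evidence matches the dense reconstruction", {
  g <- filter_grid(16L)
  th_s <- rand_theta("alds", g, 21)
  th_f <- rand_theta("aldf", g, 22)
  pr <- aldsf_cov(th_s, th_f, g)
  C <- prior_matrix(pr)
  expect_lt(max(abs(C - t(C))), 1e-12)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * sum(diag(C)) / 16)
  inst <- rand_instance(25, 16, seed = 23)
  expect_equal(log_evidence(inst$ss, pr, 0.5),
               ev_oracle_nspace(inst$X, C, 0.5, inst$y), tolerance = 1e-8)
  # identity sandwich: broad regions at zero scale give the ridge prior
  flat_s <- c(0, (g$shape - 1) / 2, 1e16)
  flat_f <- c(0, 0, 1e16)
  expect_lt(max(abs(prior_matrix(aldsf_cov(flat_s, flat_f, g)) - diag(16))),
            1e-6)
})

test_that("ALDsf degenerates to ALDf, ALDs, and ridge as regions broaden", {
  g <- filter_grid(10L)
  inst <- rand_instance(30, 10, seed = 41)
  s2 <- 0.5
  th_s <- c(0.4, 4.5, 6)       # genuinely localized in space
  th_f <- c(0.3, 1.5, 2)       # genuinely localized in frequency
  flat_s <- c(0, 4.5, 1e12)
  flat_f <- c(0, 0, 1e12)
  ev <- function(pr) log_evidence(inst$ss, pr, s2)
  expect_equal(ev(aldsf_cov(flat_s, th_f, g)),
               ev(aldf_cov(th_f[1], th_f[2], th_f[3], g)), tolerance = 1e-6)
  expect_equal(ev(aldsf_cov(th_s, flat_f, g)),
               ev(alds_cov(th_s[1], th_s[2], th_s[3], g)), tolerance = 1e-6)
  expect_equal(ev(aldsf_cov(flat_s, flat_f, g)),
               ev(ridge_cov(0, 10)), tolerance = 1e-6)
})

test_that("every family's dC/dtheta matches finite differences of the
           covariance itself", {
  g <- filter_grid(c(3, 3))
  h <- 1e-5
  for (fam in c("ridge", "ard", "asd", "alds", "aldf", "aldsf")) {
    th <- rand_theta(fam, g, seed = 61)
    hp <- hyperparams(fam, th, 1, d = 2, D = 9)
    pr <- build_prior(hp, g)
    Cmat <- function(x) {
      prior_matrix(build_prior(hyperparams(fam, x, 1, d = 2, D = 9), g))
    }
    for (j in seq_along(th)) {
      xp <- th; xp[j] <- xp[j] + h
      xm <- th; xm[j] <- xm[j] - h
      fd <- (Cmat(xp) - Cmat(xm)) / (2 * h)
      dC <- pr$dtheta[[j]]
      an <- switch(pr$form,
        diag = diag(dC$diag, 9),
        dense = dC$dense,
        freq_diag = {
          B <- pr$basis$B
          t(B) %*% diag(dC$diag, 9) %*% B
        },
        sandwich = {
          B <- pr$basis$B
          Q <- t(B) %*% diag(pr$cf, 9) %*% B
          if (!is.null(dC$dms)) {
            half <- dC$dms * t(pr$ms * Q) # dMs Q Ms
            half + t(half)
          } else {
            pr$ms * t(pr$ms * (t(B) %*% diag(dC$dcf, 9) %*% B))
          }
        })
      expect_equal(an, fd, tolerance = 1e-4 * max(1, max(abs(fd))),
                   label = paste(fam, "theta", j))
    }
  }
})

test_that("pruning deactivates small-variance directions without moving
           the evidence", {
  pr <- ard_cov(-log(c(1, 1e-12)))
  expect_equal(prune_active(pr, 1e-8), c(TRUE, FALSE))
  pr2 <- ard_cov(-log(c(1, 0.9, 0.1)))
  expect_equal(prune_active(pr2, 0.5), c(TRUE, TRUE, FALSE))
  expect_error(prune_active(ridge_cov(60, 3), 2), "threshold")
  # evidence invariance under the default threshold, ALDs instance
  g <- filter_grid(20L)
  inst <- rand_instance(30, 20, seed = 71)
  pr3 <- alds_cov(0.2, 9.5, 2, g) # strongly localized: tails prunable
  le_pruned <- log_evidence(inst$ss, pr3, 0.5, prune_threshold = 1e-10)
  le_full <- log_evidence(inst$ss, pr3, 0.5, prune_threshold = 1e-300)
  expect_lt(abs(le_pruned - le_full), 1e-6)
})
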