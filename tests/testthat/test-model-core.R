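test_that("sufficient statistics match direct products, chunked or not", {
  # identity design
  s1 <- sufficient_stats(diag(2), c(1, 2))
  expect_equal(s1$xtx, diag(2))
  expect_equal(s1$xty, c(1, 2))
  expect_equal(s1$yty, 5)
  expect_equal(s1$n, 2L)
  # null design
  s0 <- sufficient_stats(matrix(0, 3, 2), c(1, 1, 1))
  expect_equal(s0$xtx, matrix(0, 2, 2))
  expect_equal(s0$xty, c(0, 0))
  expect_equal(s0$yty, 3)
  # chunked accumulation equals the one-shot product
  set.seed(3)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- rnorm(50)
  a <- sufficient_stats(X, y)
  b <- sufficient_stats(X, y, chunk_size = 7)
  expect_equal(a$xtx, b$xtx, tolerance = 1e-12)
  expect_equal(a$xty, b$xty, tolerance = 1e-12)
  expect_error(sufficient_stats(X, y[-1]), "dimension mismatch")
})

test_that("ML estimate solves the normal equations and flags rank deficiency", {
  expect_equal(ml_estimate(suffstats(diag(2), c(1, 2), 5, 2)), c(1, 2))
  expect_equal(ml_estimate(suffstats(diag(c(1, 2)), c(2, 2), 8, 2)), c(2, 1))
  set.seed(4)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rnorm(40)
  ss <- sufficient_stats(X, y)
  expect_equal(ml_estimate(ss), solve(crossprod(X), crossprod(X, y))[, 1],
               tolerance = 1e-8)
  # rank-deficient Gram matrix names the number of deficient dimensions
  Xs <- cbind(X[, 1:9], X[, 9])
  expect_error(ml_estimate(sufficient_stats(Xs, y)), "1 deficient")
})

test_that("posterior recovers the ML and zero limits and the dense oracle", {
  ss <- sufficient_stats(diag(2), c(3, -1))
  vague <- posterior_moments(ss, diag(1e6, 2), 1)
  expect_equal(vague$mean, c(3, -1), tolerance = 1e-3)
  tight <- posterior_moments(ss, diag(1e-8, 2), 1)
  expect_lt(sqrt(sum(tight$mean^2)), 1e-5 * sqrt(sum(c(3, -1)^2)))
  expect_error(posterior_moments(ss, diag(2), -1), "positive")
  # random instance vs brute-force dense formula
  inst <- rand_instance(5, 8, seed = 9)
  set.seed(10)
  A <- matrix(rnorm(64), 8, 8)
  C <- crossprod(A) / 8 + diag(0.1, 8)
  o <- posterior_oracle_dense(inst$ss, C, 0.4)
  p <- posterior_moments(inst$ss, C, 0.4)
  expect_equal(p$mean, o$mean, tolerance = 1e-8)
  expect_lt(max(abs(p$cov - o$cov)), 1e-8)
})

test_that("log evidence matches closed forms and the n-space oracle", {
  # single observation, zero prior mass: standard normal density at 0
  ss1 <- suffstats(matrix(1), 0, 0, 1)
  expect_equal(log_evidence(ss1, matrix(0), 1), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # C = 0 closed form
  inst <- rand_instance(6, 3, seed = 2)
  expect_equal(log_evidence(inst$ss, matrix(0, 3, 3), 0.7),
               -0.5 * (6 * log(2 * pi * 0.7) + inst$ss$yty / 0.7),
               tolerance = 1e-10)
  expect_error(log_evidence(inst$ss, -diag(3), 1), "positive semi-definite")
  # every family, random small instances, D-space Woodbury vs n-space
  g <- filter_grid(c(3, 4))
  for (fam in c("ridge", "ard", "asd", "alds", "aldf", "aldsf")) {
    for (sd_ in 1:3) {
      inst <- rand_instance(7 + sd_, 12, seed = 100 + sd_)
      hp <- hyperparams(fam, rand_theta(fam, g, 200 + sd_), 0.6, d = 2,
                        D = 12)
      pr <- build_prior(hp, g)
      expect_equal(log_evidence(inst$ss, pr, 0.6),
                   ev_oracle_nspace(inst$X, prior_matrix(pr), 0.6, inst$y),
                   tolerance = 1e-8)
    }
  }
})

test_that("analytic evidence gradients match central finite differences", {
  g <- filter_grid(c(3, 4))
  for (fam in c("asd", "alds", "aldf", "aldsf")) {
    inst <- rand_instance(15, 12, seed = 31)
    th <- rand_theta(fam, g, seed = 37)
    hp <- hyperparams(fam, th, 0.5, d = 2)
    gh <- evidence_grad_hess(inst$ss, hp, g, hessian = FALSE)
    f <- function(x) {
      log_evidence(inst$ss,
                   build_prior(hyperparams(fam, x[-length(x)],
                                           x[length(x)], d = 2), g),
                   x[length(x)])
    }
    fd <- fd_gradient(f, c(th, 0.5))
    expect_equal(unname(gh$gradient), fd,
                 tolerance = 1e-4 * max(1, max(abs(fd))))
  }
})

test_that("the Hessian is symmetric by construction", {
  g <- filter_grid(8L)
  inst <- rand_instance(20, 8, seed = 55)
  hp <- hyperparams("alds", rand_theta("alds", g, 56), 0.4, d = 1)
  gh <- evidence_grad_hess(inst$ss, hp, g)
  H <- gh$hessian
  expect_lt(max(abs(H - t(H))), 1e-10 * max(abs(H)))
})

test_that("ridge shrinkage is monotone and the vague limit hits ML", {
  inst <- rand_instance(40, 6, seed = 77)
  norms <- vapply(seq(-4, 6, length.out = 12), function(rho) {
    sqrt(sum(posterior_moments(inst$ss, ridge_cov(rho, 6), 0.5,
                               cov = FALSE)$mean^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  wml <- ml_estimate(inst$ss)
  mu <- posterior_moments(inst$ss, diag(1e8, 6), 0.5, cov = FALSE)$mean
  expect_equal(mu, wml, tolerance = 1e-4)
})
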