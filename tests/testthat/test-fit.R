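test_that("ridge fixed point recovers generative hyperparameters", {
  D <- 20; lam_true <- 4; s2_true <- 0.5
  lams <- s2s <- numeric(10)
  for (k in 1:10) {
    set.seed(400 + k)
    X <- matrix(rnorm(2000 * D), 2000, D)
    w <- rnorm(D, 0, sqrt(1 / lam_true))
    y <- drop(X %*% w) + rnorm(2000, 0, sqrt(s2_true))
    fit <- fit_ridge_eb(sufficient_stats(X, y))
    lams[k] <- exp(fit$hyperparams$theta[["rho"]])
    s2s[k] <- fit$hyperparams$noise_var
  }
  expect_lt(max(median(lams) / lam_true, lam_true / median(lams)), 1.5)
  expect_lt(abs(median(s2s) - s2_true) / s2_true, 0.1)
})

test_that("ridge fixed point is a stationary point matching a grid oracle", {
  inst <- rand_instance(120, 10, seed = 81, noise_sd = 1)
  fit <- fit_ridge_eb(inst$ss)
  s2 <- fit$hyperparams$noise_var
  rho_hat <- fit$hyperparams$theta[["rho"]]
  f <- function(r) log_evidence(inst$ss, ridge_cov(r, 10), s2)
  h <- 1e-4
  expect_lt(abs((f(rho_hat + h) - f(rho_hat - h)) / (2 * h)), 1e-3)
  # 200-point log grid over lambda cannot beat the fixed point by > 1e-3
  grid_best <- max(vapply(seq(-15, 15, length.out = 200), f, numeric(1)))
  expect_gt(fit$posterior$log_evidence, grid_best - 1e-3)
  # evidence trace is non-decreasing up to tolerance
  expect_true(all(diff(fit$trace) > -1e-8))
})

test_that("ARD beats ML on sparse filters and prunes dead inputs", {
  errs <- matrix(NA_real_, 10, 2)
  for (k in 1:10) {
    set.seed(500 + k)
    D <- 50
    w <- numeric(D); w[sample(D, 5)] <- rnorm(5, 0, 1)
    X <- matrix(rnorm(800 * D), 800, D)
    y <- drop(X %*% w) + rnorm(800, 0, sqrt(0.3))
    ss <- sufficient_stats(X, y)
    fit <- fit_ard_eb(ss)
    errs[k, ] <- c(filter_error(w, fit$estimate),
                   filter_error(w, ml_estimate(ss)))
    expect_true(all(diff(fit$trace) > -1e-6))
  }
  expect_lt(median(errs[, 1]), median(errs[, 2]))
  # identically-zero stimulus column is pruned to an exact zero
  set.seed(2)
  X <- cbind(matrix(rnorm(200 * 3), 200, 3), 0)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(200, 0, 0.5)
  fit0 <- fit_ard_eb(sufficient_stats(X, y))
  expect_false(fit0$posterior$active[4])
  expect_identical(fit0$estimate[4], 0)
})

test_that("ARD fixed point attains the 2-D grid-oracle evidence", {
  set.seed(91)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- drop(X %*% c(1.2, 0)) + rnorm(60, 0, 0.6)
  ss <- sufficient_stats(X, y)
  fit <- fit_ard_eb(ss)
  s2 <- fit$hyperparams$noise_var
  grid_best <- max(outer(
    seq(-12, 12, length.out = 70), seq(-12, 12, length.out = 70),
    Vectorize(function(r1, r2) log_evidence(ss, ard_cov(c(r1, r2)), s2))
  ))
  expect_gt(fit$posterior$log_evidence, grid_best - 1e-3)
})

test_that("evidence optimization never returns less evidence than its
           initialization and recovers the 1-D filter ordering", {
  g <- filter_grid(100L)
  w <- dog_1d(100)
  errs <- matrix(NA_real_, 8, 3,
                 dimnames = list(NULL, c("aldsf", "asd", "ml")))
  for (k in 1:8) {
    X <- gen_stimuli("one_over_f", 2000, g, seed = 600 + k)
    wk <- w / sd(drop(X %*% w))
    y <- simulate_responses(X, wk, 0.3, seed = 700 + k)
    ss <- sufficient_stats(X, y)
    init <- initialize_ald(ss, g, "asd")
    f_asd <- fit_evidence_opt(ss, g, "asd", init = init)
    le_init <- log_evidence(ss, build_prior(init, g), init$noise_var)
    expect_gte(f_asd$posterior$log_evidence, le_init)
    f_sf <- fit_evidence_opt(ss, g, "aldsf")
    errs[k, ] <- c(filter_error(wk, f_sf$estimate),
                   filter_error(wk, f_asd$estimate),
                   filter_error(wk, ml_estimate(ss)))
  }
  med <- apply(errs, 2, median)
  expect_lt(med["aldsf"], med["asd"])
  expect_lt(med["asd"], med["ml"])
})

test_that("ALDs optimizer attains a (nu, psi) grid-oracle evidence", {
  g <- filter_grid(24L)
  w <- dog_1d(24, center = 11.5, s1 = 2, s2 = 4)
  X <- gen_stimuli("white", 300, g, seed = 3)
  y <- simulate_responses(X, w, 0.3, seed = 4)
  ss <- sufficient_stats(X, y)
  fit <- fit_evidence_opt(ss, g, "alds")
  th <- fit$hyperparams$theta
  s2 <- fit$hyperparams$noise_var
  grid_best <- max(outer(
    seq(2, 22, length.out = 40), seq(0.5, 200, length.out = 60),
    Vectorize(function(nu, psi) {
      log_evidence(ss, alds_cov(th[["rho_s"]], nu, psi, g), s2)
    })
  ))
  expect_gt(fit$posterior$log_evidence, grid_best - 1e-2)
})

test_that("initialization heuristics find centers of mass and power", {
  # symmetric filter about pixel 50 on a 101-pixel grid, identity design
  g <- filter_grid(101L)
  w <- exp(-((0:100) - 50)^2 / (2 * 6^2))
  ss <- sufficient_stats(diag(101), w)
  init_s <- initialize_ald(ss, g, "alds")
  expect_equal(init_s$theta[["nu_s1"]], 50, tolerance = 1e-6)
  # pure cosine at frequency 4: Fourier power centroid at |omega| = 4
  g2 <- filter_grid(32L)
  w2 <- cos(2 * pi * 4 * (0:31) / 32)
  ss2 <- sufficient_stats(diag(32), w2)
  init_f <- initialize_ald(ss2, g2, "aldf")
  expect_equal(init_f$theta[["nu_f1"]], 4, tolerance = 1e-6)
  # the chosen grid candidate maximizes evidence among those evaluated
  rec <- attr(init_f, "record")
  expect_equal(rec$chosen, which.max(rec$evidence))
})

test_that("estimates are equivariant under response rescaling", {
  g <- filter_grid(16L)
  w <- dog_1d(16, center = 7.5, s1 = 1.5, s2 = 3)
  X <- gen_stimuli("white", 400, g, seed = 7)
  y <- simulate_responses(X, w, 0.3, seed = 8)
  c_ <- 3.7
  for (fam in c("ridge", "alds")) {
    f1 <- ald_fit(sufficient_stats(X, y), shape = g, family = fam)
    f2 <- ald_fit(sufficient_stats(X, c_ * y), shape = g, family = fam)
    expect_equal(f2$hyperparams$noise_var, c_^2 * f1$hyperparams$noise_var,
                 tolerance = 1e-4)
    expect_equal(f2$estimate, c_ * f1$estimate, tolerance = 1e-4)
  }
})

test_that("posterior log evidence stored in a fit matches a recomputation", {
  inst <- rand_instance(80, 12, seed = 15, noise_sd = 1)
  g <- filter_grid(12L)
  fit <- fit_evidence_opt(inst$ss, g, "alds")
  le <- log_evidence(inst$ss, build_prior(fit$hyperparams, g),
                     fit$hyperparams$noise_var)
  expect_equal(fit$posterior$log_evidence, le, tolerance = 1e-8)
})
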