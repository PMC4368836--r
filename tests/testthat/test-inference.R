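test_that("ensemble sampling respects pool limits and is uniform", {
  sp <- data.frame(trial = 1L, neuron = 1L, time = 0.01)
  tr <- data.frame(trial = 1:2, s = c(25, 35), choice = NA, pool = "1")
  ds <- spike_dataset(sp, tr, pools = list("1" = 1:170), T = 0.1, s0 = 30)
  ens <- sample_ensembles(ds, K = 150, n_ensembles = 5, I = 20, seed = 1)
  expect_length(ens, 5)
  expect_true(all(vapply(ens, function(e)
    length(intersect(e$ensemble, e$iset)) == 0, logical(1))))
  expect_error(sample_ensembles(ds, K = 160, n_ensembles = 2, I = 20),
               "exceeds")
  ## determinism under a fixed seed
  e1 <- sample_ensembles(ds, 10, 3, 5, seed = 9)
  e2 <- sample_ensembles(ds, 10, 3, 5, seed = 9)
  expect_identical(e1, e2)
  ## inclusion frequency ~ K / pool size
  ens2 <- sample_ensembles(ds, K = 17, n_ensembles = 600, I = 3, seed = 2)
  freq <- table(factor(unlist(lapply(ens2, `[[`, "ensemble")), levels = 1:170))
  expect_equal(mean(freq) / 600, 17 / 170, tolerance = 1e-10)
  expect_lt(max(abs(freq / 600 - 0.1)), 4 * sqrt(0.1 * 0.9 / 600))
})

test_that("empirical-Bayes ridge vanishes with data and kicks in when rank-deficient", {
  set.seed(3)
  N <- 12
  A <- matrix(rnorm(N^2), N); Cbb <- crossprod(A) / N + diag(N)
  bbar <- rnorm(N, 0, 0.3)
  lam_small_n <- choose_regularization(Cbb, bbar, n_trials = 30)
  lam_big_n <- choose_regularization(Cbb, bbar, n_trials = 3e5)
  expect_lt(lam_big_n, lam_small_n / 5)
  expect_lt(lam_big_n / mean(diag(Cbb)), 0.01)
  ## singular covariance (as with K > n_trials): strictly positive ridge
  X <- matrix(rnorm(5 * N), 5, N)
  Csing <- crossprod(scale(X, scale = FALSE)) / 4
  lam_sing <- choose_regularization(Csing, bbar, n_trials = 5)
  expect_gt(lam_sing, 1e-6 * mean(diag(Csing)))
  ## the chosen ridge never predicts a smaller JND than lambda = 0
  ist <- list(bbar = bbar, Cbb = Cbb, sigma_s2 = 1)
  expect_gte(predict_jnd(ist, lambda = lam_small_n),
             predict_jnd(ist, lambda = 0))
  expect_error(choose_regularization(-Cbb, bbar, 10), "positive semi-definite")
})

test_that("bi-temporal smoothing preserves constants and mass", {
  q0 <- matrix(2.5, 30, 30)
  expect_equal(smooth_q(q0, 0.01, 0.01), q0, tolerance = 1e-10)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- smooth_q(imp, 0.01, 0.01)
  expect_equal(sum(sm), 1, tolerance = 1e-6)       # mass preserved
  expect_lt(sm[21, 21], 1)                          # spread out
  expect_equal(sm, t(sm), tolerance = 1e-12)        # symmetric field stays so
  ## signal away from edges: integral preserved within 1%
  set.seed(5)
  q <- matrix(0, 40, 40)
  q[15:25, 15:25] <- abs(rnorm(121))
  expect_lt(abs(sum(smooth_q(q, 0.01, 0.01)) - sum(q)) / sum(q), 0.01)
})

test_that("V debiasing removes the measurement-noise inflation", {
  set.seed(7)
  N <- 200
  bbar_true <- rnorm(N)
  ## pure-noise CC (choice-shuffled analogue): true V would be 0 with d = 0
  nboot <- 30
  noise_sd <- 0.4
  dbar_noise <- rnorm(N, 0, noise_sd)
  boot_b <- matrix(rnorm(N * nboot, bbar_true, 0.05), N)
  boot_d <- matrix(rnorm(N * nboot, 0, noise_sd), N)
  raw <- indicator_V(bbar_true, dbar_noise)
  cor <- debias_V(bbar_true, dbar_noise, boot_b, boot_d)
  expect_gt(raw, 0.05)
  expect_lt(abs(cor$V), raw / 3)
  ## noiseless inputs: identical resamples, correction is exactly zero
  dbar <- 0.3 * bbar_true + rnorm(N, 0, 0.01)
  bb0 <- matrix(rep(bbar_true, 4), N)
  dd0 <- matrix(rep(dbar, 4), N)
  cor0 <- debias_V(bbar_true, dbar, bb0, dd0)
  expect_equal(cor0$V, cor0$V_raw, tolerance = 1e-12)
  expect_warning(debias_V(bbar_true, dbar), "bootstrap")
})

test_that("the Case-1 loss vanishes at the generative readout and grows away from it", {
  ist <- random_istats(n_neurons = 5, seed = 11)
  kap <- 0.07; sigma_d <- 0.8
  a <- optimal_readout(ist, lambda = 0)
  S <- attr(a, "S")
  Z_star <- sqrt(S + sigma_d^2)
  d_star <- kap * predict_moments(as.numeric(a), ist)$cov_t
  L0 <- loss_case1(ist, d_star, Z_star, as.numeric(a), sigma_d,
                   lambda_w = 1, mu_w = 1, kappa_star = kap)
  expect_equal(L0, 0, tolerance = 1e-12)
  ## zero readout: closed-form value
  Lz <- loss_case1(ist, d_star, Z_star, rep(0, 5), 0, lambda_w = 2,
                   mu_w = 3, kappa_star = kap)
  expect_equal(Lz, 1 + 2 * Z_star^4 + 3 * sum(d_star^2) * ist$delta,
               tolerance = 1e-10)
  ## local perturbations strictly increase the loss
  set.seed(12)
  for (i in 1:10) {
    ap <- as.numeric(a) + rnorm(5, 0, 0.05 * sd(a))
    expect_gt(loss_case1(ist, d_star, Z_star, ap, sigma_d,
                         kappa_star = kap), L0)
  }
})

test_that("predicted indicators move the right way with sigma_d and K", {
  sim <- small_experiment()
  p_small <- predict_indicators(sim$data, K = 10, w = 0.05, t_R = 0.1,
                                sigma_d = 0, n_ensembles = 30, seed = 3)
  p_big <- predict_indicators(sim$data, K = 40, w = 0.05, t_R = 0.1,
                              sigma_d = 0, n_ensembles = 30, seed = 3)
  ## more neurons, more information: smaller predicted Z^2
  expect_lt(p_big$Z2, p_small$Z2)
  ## V decreases towards global optimality as K grows
  expect_lt(p_big$V, p_small$V)
  ## sigma_d enters Z^2 additively
  p_sd <- predict_indicators(sim$data, K = 10, w = 0.05, t_R = 0.1,
                             sigma_d = 2, n_ensembles = 30, seed = 3)
  expect_equal(p_sd$Z2 - p_small$Z2, 4, tolerance = 1e-8)
})

test_that("the grid search recovers the temporal parameters of a known readout", {
  sim <- small_experiment()
  grid <- readout_grid(K = c(10, 20, 30, 40), w = c(0.03, 0.05, 0.07),
                       t_R = c(0.06, 0.10, 0.14), sigma_d = c(0, 1, 2),
                       n_ensembles = 40)
  fit <- fit_readout_scales(sim$data, grid, seed = 11)
  expect_s3_class(fit, "readout_fit")
  expect_equal(unname(fit$best[["w"]]), 0.05)
  expect_equal(unname(fit$best[["t_R"]]), 0.10)
  expect_lte(abs(fit$best[["K"]] - sim$truth$K), 20)
  ## grid containing only the generative cell returns it
  g1 <- readout_grid(K = 20, w = 0.05, t_R = 0.1, sigma_d = 1,
                     n_ensembles = 20)
  f1 <- fit_readout_scales(sim$data, g1, seed = 5)
  expect_equal(unname(f1$best),
               c(0.05, 0.1, 20, 1), tolerance = 1e-12)
  ## K-w trade-off: predicted Z^2 falls with K and with w
  S <- fit$S_bar
  expect_true(all(apply(S[, 2, ], 1, diff) < 0))      # in K
  expect_true(all(apply(S[, 2, ], 2, diff) < 0))      # in w
  ## determinism: identical master seed, identical result
  fit2 <- fit_readout_scales(sim$data, grid, seed = 11)
  expect_identical(fit$best, fit2$best)
  expect_identical(fit$loss, fit2$loss)
  ## summary and print run
  expect_output(print(fit), "best fit")
  expect_output(print(summary(fit)), "JND")
})

test_that("bootstrap refits produce scatter and confidence ellipses", {
  sim <- small_experiment()
  grid <- readout_grid(K = c(10, 20, 30), w = c(0.03, 0.05, 0.07),
                       t_R = c(0.06, 0.10, 0.14), sigma_d = c(0, 1),
                       n_ensembles = 15)
  bt <- bootstrap_fit(sim$data, grid, n_boot = 3, seed = 21, n_vboot = 4)
  expect_equal(dim(bt$fits), c(3L, 4L))
  expect_true(all(is.finite(bt$fits)))
  expect_length(bt$ellipses, 3)
  expect_equal(colnames(bt$ellipses[[1]]$sd2), c("t_R", "w"))
  expect_output(print(bt), "bootstrap")
})
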