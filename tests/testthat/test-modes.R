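test_that("SVD modes reconstruct the data and satisfy orthonormality", {
  set.seed(4)
  rb <- matrix(rnorm(200 * 12, 20, 3), 200, 12)
  md <- svd_modes(rb)
  expect_equal(crossprod(md$U), diag(md$M), tolerance = 1e-10)
  expect_equal(crossprod(md$v) / md$n_trials, diag(md$M), tolerance = 1e-10)
  rec <- sweep(md$v %*% (md$lambda * t(md$U)), 2, md$r0, "+")
  expect_equal(rec, rb, tolerance = 1e-8)
  ## total covariance identity A = U Lambda^2 U^T (1/n convention)
  A <- crossprod(sweep(rb, 2, colMeans(rb))) / nrow(rb)
  expect_equal(md$U %*% (md$lambda^2 * t(md$U)), A, tolerance = 1e-8)
})

test_that("a rank-1 population yields a single mode with the right shape", {
  set.seed(6)
  u <- rnorm(15); u <- u / sqrt(sum(u^2))
  g <- rnorm(80)
  rb <- outer(g, u)
  md <- svd_modes(rb)
  expect_equal(md$M, 1L)
  expect_equal(abs(sum(md$U[, 1] * u)), 1, tolerance = 1e-10)
  expect_equal(svd_modes(matrix(0, 10, 5))$M, 0L)
})

test_that("white-noise activity has no dominant mode", {
  set.seed(7)
  rb <- matrix(rnorm(400 * 20), 400, 20)
  md <- svd_modes(rb)
  ## Marchenko-Pastur-like spread: power ratio bounded, no isolated mode
  expect_lt(md$lambda[1]^2 / md$lambda[md$M]^2, 6)
  expect_lt(md$lambda[1]^2 / sum(md$lambda^2), 0.15)
})

test_that("mode tuning agrees between the regression and algebraic routes", {
  sim <- small_experiment()
  kern <- sim$truth$kernel
  ist <- integrated_statistics(sim$data, kern, pool = "1")
  md <- svd_modes(ist$rbar)
  s <- ist$trials$s
  mt <- mode_tuning(md, s, bbar = ist$bbar)
  expect_equal(mt$eta, mt$eta_b, tolerance = 1e-8)
  expect_equal(mt$Y_tot, mt$sigma_s2 * sum(mt$eta^2), tolerance = 1e-12)
  ## untuned population: all mode sensitivities near zero
  set.seed(11)
  rb0 <- matrix(rnorm(300 * 10, 20, 2), 300, 10)
  md0 <- svd_modes(rb0)
  mt0 <- mode_tuning(md0, rep(c(25, 30, 35), 100))
  expect_lt(max(mt0$y), 0.05)
  expect_error(mode_tuning(md0, rep(30, 300)), "2 stimuli")
})

test_that("observation fractions satisfy trace, growth and saturation laws", {
  set.seed(13)
  lam <- 5 * (1:8)^(-0.7)
  U <- qr.Q(qr(matrix(rnorm(40 * 8), 40, 8)))
  rb <- sweep(matrix(rnorm(500 * 8), 500) %*% (lam * t(U)), 2,
              rep(20, 40), "+")
  md <- svd_modes(rb)
  expect_equal(md$M, 8L)
  of <- observation_fractions(md, K = c(2, 4, 6, 8, 40), n_ensembles = 100)
  ## trace property: sum_m eps_m(K) = K while K <= M, then = M
  expect_equal(colSums(of$eps), c(2, 4, 6, 8, 8), tolerance = 1e-9)
  ## growth in K
  for (m in seq_len(md$M))
    expect_true(all(diff(of$eps[m, ]) > -0.05))
  ## full population: all modes fully observed
  expect_equal(of$eps[, 5], rep(1, md$M), tolerance = 1e-9)
})

test_that("projectors are idempotent and symmetric", {
  sim <- small_experiment()
  ist <- integrated_statistics(sim$data, sim$truth$kernel, pool = "1")
  md <- svd_modes(ist$rbar)
  set.seed(17)
  for (K in c(3, 10, 25)) {
    P <- readoutscales:::.mode_projector(md, sample(md$n_neurons, K))
    expect_equal(P, t(P), tolerance = 1e-9)
    expect_equal(P %*% P, P, tolerance = 1e-9)
  }
})

test_that("exact ensemble sensitivity matches the restricted-total-covariance route", {
  sim <- small_experiment()
  ist <- integrated_statistics(sim$data, sim$truth$kernel, pool = "1")
  md <- svd_modes(ist$rbar)
  s <- ist$trials$s
  mt <- mode_tuning(md, s, bbar = ist$bbar)
  A <- md$U %*% (md$lambda^2 * t(md$U))
  bbar <- as.numeric(md$U %*% (md$lambda * mt$eta))
  pinv <- function(M) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    keep <- e$values > max(e$values) * nrow(M) * .Machine$double.eps
    e$vectors[, keep, drop = FALSE] %*%
      (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  }
  set.seed(19)
  for (rep in 1:100) {
    ens <- sample(md$n_neurons, sample(3:20, 1))
    ex <- exact_ensemble_quantities(md, mt, ens)
    Y58 <- mt$sigma_s2 *
      as.numeric(crossprod(bbar[ens], pinv(A[ens, ens]) %*% bbar[ens]))
    expect_equal(ex$Y, Y58, tolerance = 1e-6)
  }
  ## full population: CC prediction proportional to tuning, V = 0
  exf <- exact_ensemble_quantities(md, mt, seq_len(md$n_neurons))
  expect_equal(exf$Y, mt$Y_tot, tolerance = 1e-8)
  expect_equal(exf$e, mt$sigma_s2 / mt$Y_tot * bbar, tolerance = 1e-6)
  expect_equal(exf$V, 0, tolerance = 1e-10)
})

test_that("analytic curves track exact ensemble averages and saturate", {
  ## low-rank latent population where the diagonal approximation is sharp
  set.seed(13)
  N <- 50; M <- 6
  lam <- 8 * (1:M)^(-0.8)
  U <- qr.Q(qr(matrix(rnorm(N * M), N, M)))
  n <- 900
  s <- rep(c(25, 30, 35), n / 3)
  eta0 <- rnorm(M, 0, 0.15)
  v <- matrix(rnorm(n * M), n, M) + outer(s - mean(s), eta0)
  rb <- 20 + v %*% (lam * t(U)) + matrix(rnorm(n * N, 0, 0.5), n, N)
  md <- svd_modes(rb)
  mt <- mode_tuning(md, s)
  Ks <- c(5, 10, 20, 35, 50)
  set.seed(23)
  of <- observation_fractions(md, Ks, n_ensembles = 200)
  ac <- approx_curves(md, of, mt)
  expect_true(all(diff(ac$Y) > -1e-9))            # nondecreasing
  ## exact ensemble averages at each K
  set.seed(29)
  ex <- lapply(Ks, function(K)
    vapply(1:200, function(e) {
      q <- exact_ensemble_quantities(md, mt, sample(md$n_neurons, K))
      c(q$Y, q$Q)
    }, numeric(2)))
  Yex <- vapply(ex, function(m) mean(m[1, ]), numeric(1))
  Qex <- vapply(ex, function(m) mean(m[2, ]), numeric(1))
  expect_lt(max(abs(ac$Y - Yex) / Yex), 0.1)
  expect_lt(max(abs(ac$Q - Qex) / abs(Qex)), 0.1)
  ## saturation at the full-population value
  off <- observation_fractions(md, md$n_neurons)
  acf <- approx_curves(md, off, mt)
  expect_equal(acf$Y, mt$Y_tot, tolerance = 1e-8)
  ## single-mode population: Y(K) = eps_1(K) y_1
  u1 <- qr.Q(qr(matrix(rnorm(30), 30, 1)))
  rb1 <- sweep(matrix(rnorm(400), 400, 1) %*% (4 * t(u1)), 2, rep(15, 30), "+") +
    outer(rep(c(-2, 0, 2), length.out = 400), as.numeric(u1))
  md1 <- svd_modes(rb1)
  mt1 <- mode_tuning(md1, rep(c(28, 30, 32), length.out = 400))
  of1 <- observation_fractions(md1, c(3, 10), n_ensembles = 80)
  ac1 <- approx_curves(md1, of1, mt1)
  expect_equal(ac1$Y, as.numeric(crossprod(of1$eps, mt1$y)), tolerance = 1e-12)
})

test_that("sensitivity rescalings behave at their limits and invert", {
  expect_equal(sensitivity_from_jnd(0, 4), 1)
  expect_lt(sensitivity_from_jnd(1e6, 4), 1e-9)
  expect_equal(sensitivity_from_jnd(2, 4), 0.5)   # Z = sigma_s
  for (Z in c(0.5, 3, 10))
    expect_equal(jnd_from_sensitivity(sensitivity_from_jnd(Z, 50 / 3), 50 / 3),
                 Z, tolerance = 1e-10)
  expect_equal(rescale_q(0.2, 0.05, 4, 0.3), 0.2 / 0.05 + 4 * 0.3)
})
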