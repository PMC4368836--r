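test_that("PSTH recovers homogeneous Poisson rates and toy counts", {
  ds <- poisson_dataset(n_neurons = 6, rate = 20, b = 0,
                        trials_per_stim = 60, seed = 5)
  ps <- estimate_psth(ds, delta = 0.02)
  # per-bin SE of a rate estimate from n trials: sqrt(rate/delta / n)
  n <- sum(stimulus_set(ds)$n)
  se <- sqrt(20 / 0.02 / (n / 3))
  expect_lt(max(abs(ps$m - 20)), 4 * se)
  expect_lt(abs(mean(ps$m) - 20), 3 * se / sqrt(length(ps$m) / 4))

  toy <- toy_dataset()
  pt <- estimate_psth(toy, delta = 0.01)
  # neuron 1, stimulus 25: spikes at 0.02, 0.07 (trial 1), 0.05 (trial 2)
  i <- match(1, pt$neurons); k <- match(25, pt$stimuli)
  expect_equal(pt$m[i, 3, k], 50)   # 1 spike / 2 trials / 0.01
  expect_equal(pt$m[i, 1, k], 0)
})

test_that("empty stimulus groups are reported and zero spikes give zero PSTH", {
  sp <- data.frame(trial = integer(0), neuron = integer(0), time = numeric(0))
  tr <- data.frame(trial = 1:4, s = c(25, 25, 35, 35), choice = NA_integer_)
  ds <- spike_dataset(sp, tr, pools = list("1" = 1:2), T = 0.1, s0 = 30)
  ps <- estimate_psth(ds, 0.01)
  expect_true(all(ps$m == 0))
})

test_that("tuning slopes equal the weighted regression of PSTH on s", {
  toy <- toy_dataset()
  ps <- estimate_psth(toy, delta = 0.05)
  b <- estimate_tuning(ps)
  # two stimuli: slope = (m(35) - m(25)) / 10, exactly
  expect_equal(b, (ps$m[, , 2] - ps$m[, , 1]) / 10,
               ignore_attr = TRUE)
  # flat PSTH -> zero slope; exact linear means -> exact slope
  ps3 <- ps
  ps3$stimuli <- c(25, 30, 35)
  ps3$n <- cbind(ps$n, ps$n[, 1])
  ps3$m <- array(0, dim = c(nrow(b), ncol(b), 3))
  expect_equal(unique(as.numeric(estimate_tuning(ps3))), 0)
  for (k in 1:3) ps3$m[, , k] <- 1.5 * ps3$stimuli[k] + 7
  expect_equal(unique(round(as.numeric(estimate_tuning(ps3)), 10)), 1.5)
  ps1 <- ps; ps1$stimuli <- 25; ps1$m <- ps$m[, , 1, drop = FALSE]
  ps1$n <- ps$n[, 1, drop = FALSE]
  expect_error(estimate_tuning(ps1), "2 distinct stimuli")
})

test_that("JPSTH is symmetric, near zero for independent neurons, and positive under shared drive", {
  ds <- poisson_dataset(n_neurons = 4, rate = 30, trials_per_stim = 80,
                        seed = 9)
  C <- estimate_jpsth(ds, delta = 0.05)
  expect_equal(C, aperm(C, c(2, 1, 4, 3)),           # C_ij(t,u) = C_ji(u,t)
               ignore_attr = TRUE)
  # diagonal same-bin entries are across-trial variances
  expect_true(all(C[cbind(rep(1:4, each = dim(C)[3]),
                          rep(1:4, each = dim(C)[3]),
                          rep(seq_len(dim(C)[3]), 4),
                          rep(seq_len(dim(C)[3]), 4))] >= 0))
  # off-diagonal pairs: |C| below 4 SE of a covariance of independent rates
  n <- nrow(ds$trials)
  se <- sqrt((30 / 0.05)^2 / (n / 3))
  off <- C[1, 2, , ]
  expect_lt(max(abs(off)), 4 * se)

  # one strong shared mode induces positive same-time covariance
  spec <- latent_mode_spec(n_neurons = 4, n_modes = 1, baseline = rep(40, 4),
                           b = rep(0, 4), lambda = 25,
                           U = matrix(0.5, 4, 1), tau_z = 0.05, seed = 3)
  ds2 <- simulate_latent_mode_population(spec, trials = 120, seed = 4)
  C2 <- estimate_jpsth(ds2, delta = 0.05)
  same_t <- vapply(seq_len(dim(C2)[3]), function(t) C2[1, 2, t, t], numeric(1))
  expect_gt(mean(same_t), 0)
})

test_that("JPSTH errors identify never co-recorded pairs", {
  sp <- data.frame(trial = c(1L, 2L), neuron = c(1L, 2L), time = c(0.01, 0.02))
  tr <- data.frame(trial = 1:2, s = c(25, 35), choice = NA, pool = c("a", "b"))
  ds <- spike_dataset(sp, tr, pools = list(a = 1L, b = 2L), T = 0.1, s0 = 30)
  expect_error(estimate_jpsth(ds, neurons = c(1L, 2L)), "never recorded together")
})

test_that("CC curves equal the brute-force spike-count/choice covariance", {
  ds <- poisson_dataset(n_neurons = 5, rate = 25, trials_per_stim = 25,
                        seed = 13)
  set.seed(14)
  ds$trials$choice <- rbinom(nrow(ds$trials), 1, 0.5)
  delta <- 0.05
  cc <- estimate_cc(ds, delta)
  bp <- readoutscales:::.bin_pool(ds, "1", delta)
  for (k in seq_along(cc$stimuli)) {
    sel <- bp$trials$s == cc$stimuli[k]
    ch <- bp$trials$choice[sel]
    for (i in c(1, 4)) for (t in c(2, 6)) {
      r <- bp$R[sel, i, t]
      expect_equal(cc$d_s[i, t, k], mean(r * ch) - mean(r) * mean(ch),
                   tolerance = 1e-12)
    }
  }
  # stimulus-averaged curve weights stimuli by trial count
  w <- stimulus_set(ds)$n / nrow(ds$trials)
  expect_equal(cc$d[2, ], as.numeric(cc$d_s[2, , ] %*% w), tolerance = 1e-12)
})

test_that("degenerate choice groups contribute exactly zero to CC", {
  ds <- poisson_dataset(n_neurons = 3, rate = 30, trials_per_stim = 10,
                        seed = 15)
  ds$trials$choice <- ifelse(ds$trials$s == 35, 1L,
                             rbinom(nrow(ds$trials), 1, 0.5))
  cc <- estimate_cc(ds, 0.05)
  expect_true(all(cc$d_s[, , cc$stimuli == 35] == 0))
})

test_that("psychometric fit recovers noiseless probit parameters", {
  mk <- function(Z, mu, n_per = 2000, s = seq(24, 36, 2)) {
    p <- pnorm((s + mu - 30) / Z)
    tr <- do.call(rbind, lapply(seq_along(s), function(i)
      data.frame(s = s[i], choice = rep(c(1L, 0L),
                                        c(round(n_per * p[i]),
                                          n_per - round(n_per * p[i]))))))
    tr$trial <- seq_len(nrow(tr))
    spike_dataset(data.frame(trial = integer(0), neuron = integer(0),
                             time = numeric(0)),
                  tr, pools = list("1" = 1L), T = 0.1, s0 = 30)
  }
  f1 <- fit_psychometric(mk(2, 0))
  expect_equal(f1$Z, 2, tolerance = 0.02)
  expect_equal(f1$mu_d, 0, tolerance = 0.02)
  f2 <- fit_psychometric(mk(3, 1))
  expect_equal(f2$Z, 3, tolerance = 0.02)
  expect_equal(f2$mu_d, 1, tolerance = 0.03)
  # unbiased observer: fitted curve crosses 1/2 at the threshold
  expect_equal(pnorm((30 + f1$mu_d - 30) / f1$Z), 0.5, tolerance = 0.01)
  # MLE route agrees on clean data
  f3 <- fit_psychometric(mk(2, 0), method = "mle")
  expect_equal(f3$Z, 2, tolerance = 0.02)
  # perfect separation pins Z at the floor with a warning
  sep <- mk(0.01, 0, n_per = 50, s = c(20, 40))
  expect_warning(fs <- fit_psychometric(sep), "separation")
  expect_gt(fs$Z, 0)
})

test_that("quadrature and direct integrated statistics agree (two-route oracle)", {
  sim <- small_experiment()
  ds <- sim$data
  kern <- temporal_kernel("square", 0.05, 0.1)
  sub <- ds$pools[["1"]][1:6]
  ## restrict to pool 1 to have simultaneity
  tr1 <- ds$trials[ds$trials$pool == "1", ]
  ds1 <- spike_dataset(ds$spikes[ds$spikes$trial %in% tr1$trial, ],
                       tr1, pools = ds$pools["1"], T = ds$T, s0 = ds$s0)
  ns <- neural_stats(ds1, 0.01, neurons = sub)
  iq <- integrate_statistics(ns, kern)
  id <- integrated_statistics(ds1, kern)
  ii <- match(sub, id$neurons)
  expect_equal(iq$bbar, id$bbar[ii], tolerance = 1e-9)
  expect_equal(iq$Cbb, id$Cbb[ii, ii], tolerance = 1e-9)
  expect_equal(iq$dbar, id$dbar[ii], tolerance = 1e-9)
})

test_that("constant tuning passes through an untruncated kernel unchanged", {
  ns <- manual_neural_stats(beta = 2)
  ist <- integrate_statistics(ns, temporal_kernel("square", 0.05, 0.1))
  expect_equal(ist$bbar, rep(2, 3))
  expect_error(integrate_statistics(ns, temporal_kernel("square", 0.05, 5)),
               "outside the recorded window")
})

test_that("noise covariance scales as 1/w for Poisson spiking", {
  ds <- poisson_dataset(n_neurons = 6, rate = 30, trials_per_stim = 150,
                        seed = 21)
  tr <- vapply(c(0.025, 0.05, 0.1), function(w) {
    ist <- integrated_statistics(ds, temporal_kernel("square", w, 0.2))
    w * mean(diag(ist$Cbb))
  }, numeric(1))
  # w * Cbb approximately constant (= rate) across windows
  expect_lt(max(abs(tr - mean(tr))) / mean(tr), 0.1)
  expect_equal(mean(tr), 30, tolerance = 0.1)
})
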