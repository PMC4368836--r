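test_that("mode-free surrogate gives Poisson count statistics", {
  ds <- poisson_dataset(n_neurons = 8, rate = 30, trials_per_stim = 150,
                        seed = 31)
  w <- 0.1
  ist <- integrated_statistics(ds, temporal_kernel("square", w, 0.2))
  ## diagonal: Var(count)/w^2 = rate/w; off-diagonal near zero
  expect_equal(mean(diag(ist$Cbb)), 30 / w, tolerance = 0.1)
  off <- ist$Cbb[upper.tri(ist$Cbb)]
  expect_lt(mean(abs(off)) , 0.1 * 30 / w)
})

test_that("a single latent mode is recovered by the SVD", {
  set.seed(33)
  u <- qr.Q(qr(matrix(rnorm(20), 20, 1)))
  spec <- latent_mode_spec(n_neurons = 20, n_modes = 1,
                           baseline = rep(40, 20), b = rep(0, 20),
                           lambda = 30, U = u, tau_z = 0.1, seed = 33)
  ds <- simulate_latent_mode_population(spec, trials = 250, seed = 34)
  ist <- integrated_statistics(ds, temporal_kernel("square", 0.1, 0.2))
  md <- svd_modes(ist$rbar)
  expect_gt(abs(cor(md$U[, 1], as.numeric(u))), 0.9)
})

test_that("an untuned population gives an uninformative psychometric curve", {
  spec <- latent_mode_spec(n_neurons = 12, n_modes = 0,
                           baseline = rep(25, 12), b = rep(0, 12), seed = 35)
  ds <- simulate_latent_mode_population(spec, trials = 60, seed = 36)
  truth <- build_ground_truth(ds, K_star = 6, sigma_d_star = 1,
                              lambda = 0.5, seed = 37)
  ds <- generate_behavior(ds, truth, seed = 38)
  fit <- fit_psychometric(ds)
  expect_gt(fit$Z, 20)   # stimulus range is 10: no usable information
})

test_that("infeasible latent specs are rejected", {
  expect_error(
    latent_mode_spec(n_neurons = 3, n_modes = 0, baseline = c(1, 1, 1),
                     b = c(2, 0, 0)),
    "negative mean rate")
})

test_that("ground-truth construction matches the scalar case and is stable", {
  ds <- poisson_dataset(n_neurons = 6, rate = 25, b = 0.8,
                        trials_per_stim = 300, seed = 41)
  t1 <- build_ground_truth(ds, K_star = 1, sigma_d_star = 0, lambda = 0,
                           seed = 42)
  ist <- integrated_statistics(ds, t1$kernel)
  i <- match(t1$ensemble, ist$neurons)
  ## scalar Fisher readout: a = 1 / bbar (weights are ensemble-indexed)
  expect_equal(t1$a[1] * ist$bbar[i], 1, tolerance = 0.35)
  expect_error(build_ground_truth(ds, K_star = 500), "2 \\* K_star")
  ## readout direction is stable under more calibration data
  ds2 <- poisson_dataset(n_neurons = 6, rate = 25, b = 0.8,
                         trials_per_stim = 160, seed = 43)
  tA <- build_ground_truth(ds2, K_star = 4, sigma_d_star = 0,
                           ensemble = 1:4, seed = 44)
  tB <- build_ground_truth(ds, K_star = 4, sigma_d_star = 0,
                           ensemble = 1:4, seed = 45)
  csim <- sum(tA$a * tB$a) / sqrt(sum(tA$a^2) * sum(tB$a^2))
  expect_gt(csim, 0.9)
})

test_that("generated behavior closes the loop with the decision model", {
  spec <- latent_mode_spec(n_neurons = 40, n_modes = 5,
                           stimuli = c(20, 30, 40),
                           b = seq(-0.7, 0.7, length.out = 40), seed = 47)
  ds <- simulate_latent_mode_population(spec, trials = 200, seed = 48)
  truth <- build_ground_truth(ds, K_star = 25, sigma_d_star = 0,
                              w_star = 0.05, t_R_star = 0.1, seed = 49)
  ds <- generate_behavior(ds, truth, seed = 50)
  psi <- aggregate(choice ~ s, ds$trials, mean)
  ## noiseless decisions on well-separated stimuli: near-perfect endpoints
  expect_lt(psi$choice[1], 0.2)
  expect_gt(psi$choice[3], 0.8)
  ## fitted JND agrees with the discriminant prediction
  fitZ <- fit_psychometric(ds)$Z
  expect_equal(fitZ, truth$Z, tolerance = 0.35)
})

test_that("pool splitting keeps schema and trial balance", {
  ds <- poisson_dataset(n_neurons = 12, rate = 20, trials_per_stim = 30,
                        seed = 51)
  pooled <- split_recording_pools(ds, n_pools = 3, pool_size = 5, seed = 52)
  expect_length(pooled$pools, 3)
  expect_true(all(lengths(pooled$pools) == 5))
  ## every spike's neuron is in its trial's pool (constructor validates too)
  pool_of <- setNames(pooled$trials$pool, pooled$trials$trial)
  ok <- mapply(function(tr, ne) ne %in% pooled$pools[[pool_of[[as.character(tr)]]]],
               pooled$spikes$trial, pooled$spikes$neuron)
  expect_true(all(ok))
  ## trial blocks are disjoint and stratified by stimulus
  tab <- table(pooled$trials$pool, pooled$trials$s)
  expect_true(all(tab == 30 / 3))
  ## single full pool leaves the spikes untouched
  same <- split_recording_pools(ds, 1, length(ds$neurons), seed = 53)
  expect_equal(nrow(same$spikes), nrow(ds$spikes))
})

test_that("LIF network is silent without drive and tuned with it", {
  spec0 <- lif_network_spec(n_inputs = 20, n_neurons = 30, n_exc_input = 10,
                            n_inh_input = 10, w_input = 0, w_scale = 0,
                            noise_sd = 0, T = 0.2)
  ds0 <- simulate_lif_network(spec0, trials = 2, bias = 0, seed = 61)
  expect_equal(nrow(ds0$spikes), 0)
  spec <- lif_network_spec(n_inputs = 100, n_neurons = 60, n_exc_input = 20,
                           n_inh_input = 20, T = 0.3)
  ds <- simulate_lif_network(spec, trials = 25, seed = 62)
  expect_gt(attr(ds, "mean_rate"), 1)
  ist <- integrated_statistics(ds, temporal_kernel("square", 0.15, 0.3))
  gr <- attr(ds, "groups")
  expect_gt(mean(ist$bbar[gr$exc_input]), 0)
  expect_lt(mean(ist$bbar[gr$inh_input]), 0)
})

test_that("the fused experiment reproduces the separate-operations route", {
  sim <- small_experiment()
  expect_s3_class(sim$data, "spike_dataset")
  expect_equal(sort(unique(sim$data$trials$pool)), c("1", "2"))
  ## choices depend on the ensemble neurons: psychometric slope is real
  psy <- fit_psychometric(sim$data)
  expect_lt(psy$Z, 12)
  expect_gt(psy$Z, 1)
  ## determinism under the master seed
  spec <- latent_mode_spec(n_neurons = 150, n_modes = 15, seed = 2)
  sim2 <- simulate_experiment(spec, K_star = 20, w_star = 0.05,
                              t_R_star = 0.1, sigma_d_star = 1, n_pools = 2,
                              pool_size = 60, trials_per_stim = 60,
                              n_calibration_per_stim = 80, seed = 7)
  expect_identical(sim2$data$trials$choice, sim$data$trials$choice)
  expect_identical(sim2$truth$a, sim$truth$a)
})
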