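# Shared fixtures, all generated in code under fixed seeds.

# homogeneous (optionally tuned) Poisson population without latent modes
poisson_dataset <- function(n_neurons = 8, rate = 20, b = 0,
                            trials_per_stim = 60, stimuli = c(25, 30, 35),
                            T = 0.4, seed = 1) {
  spec <- latent_mode_spec(n_neurons = n_neurons, n_modes = 0,
                           stimuli = stimuli, s0 = mean(stimuli), T = T,
                           baseline = rep(rate, n_neurons),
                           b = rep(b, length.out = n_neurons),
                           seed = seed)
  simulate_latent_mode_population(spec, trials = trials_per_stim, seed = seed)
}

# a tiny deterministic dataset with hand-placed spikes
toy_dataset <- function() {
  spikes <- data.frame(
    trial = c(1L, 1L, 1L, 2L, 3L, 3L, 4L),
    neuron = c(1L, 1L, 2L, 1L, 2L, 2L, 1L),
    time = c(0.02, 0.07, 0.11, 0.05, 0.03, 0.16, 0.09))
  trials <- data.frame(trial = 1:4, s = c(25, 25, 35, 35),
                       choice = c(0L, 1L, 1L, 0L))
  spike_dataset(spikes, trials, pools = list("1" = 1:2), T = 0.2, s0 = 30)
}

# hand-built neural_stats object with analytically known fields
manual_neural_stats <- function(beta = 2, n_neurons = 3, B = 20,
                                delta = 0.01) {
  breaks <- seq(0, B * delta, by = delta)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  b <- matrix(beta, n_neurons, B)
  C <- array(0, c(n_neurons, n_neurons, B, B))
  attr(C, "neurons") <- seq_len(n_neurons)
  attr(b, "neurons") <- seq_len(n_neurons)
  structure(list(
    psth = NULL, b = b,
    cc = list(d = matrix(0.5, n_neurons, B), neurons = seq_len(n_neurons)),
    C = C, mids = mids, breaks = breaks, delta = delta,
    stimuli = c(25, 30, 35), n_s = c(10, 10, 10),
    sigma_s2 = 50 / 3, s0 = 30), class = "neural_stats")
}

# random consistent integrated_stats: Cbar(t) = Cbb * g(t) with
# sum(g * kw) = 1, so quadrature of Cbar reproduces Cbb exactly
random_istats <- function(n_neurons = 6, B = 20, delta = 0.01,
                          kernel = temporal_kernel("square", 0.05, 0.1),
                          seed = 1) {
  set.seed(seed)
  breaks <- seq(0, B * delta, by = delta)
  kw <- kernel_weights(kernel, breaks)
  A <- matrix(rnorm(n_neurons^2), n_neurons)
  Cbb <- crossprod(A) / n_neurons + diag(n_neurons)
  g <- abs(rnorm(B)) + 0.2
  g <- g / sum(g * kw)
  Cbar <- array(0, c(n_neurons, n_neurons, B))
  for (t in seq_len(B)) Cbar[, , t] <- Cbb * g[t]
  bbar <- rnorm(n_neurons)
  structure(list(bbar = bbar, Cbar = Cbar, Cbb = Cbb, dbar = NULL,
                 sigma_s2 = 50 / 3, kernel = kernel,
                 neurons = seq_len(n_neurons),
                 mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
                 delta = delta, s0 = 30, stimuli = c(25, 30, 35),
                 n_s = c(10, 10, 10)),
            class = "integrated_stats")
}

# small complete validation experiment (memoized across test files)
.fixture_env <- new.env(parent = emptyenv())
small_experiment <- function() {
  if (is.null(.fixture_env$sim)) {
    spec <- latent_mode_spec(n_neurons = 150, n_modes = 15, seed = 2)
    .fixture_env$sim <- simulate_experiment(
      spec, K_star = 20, w_star = 0.05, t_R_star = 0.1, sigma_d_star = 1,
      n_pools = 2, pool_size = 60, trials_per_stim = 60,
      n_calibration_per_stim = 80, seed = 7)
  }
  .fixture_env$sim
}
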