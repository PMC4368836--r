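#' Specification of the latent-mode surrogate population
#'
#' A doubly stochastic Poisson population with controllable low-dimensional
#' correlation structure: neuron i fires with instantaneous rate
#' \deqn{rate_i(t) = base_i + b_i (s - s_0) + \sum_m \lambda_m u_i^m z_m(t),}
#' where the latent mode activations \eqn{z_m(t)} are independent
#' Ornstein-Uhlenbeck processes with unit stationary variance and
#' correlation time `tau_z`. This reproduces the features the readout
#' analysis needs — linear tuning of mixed polarity, Poisson-like count
#' variance, and a known mode structure — at a small fraction of the cost of
#' a recurrent spiking network. Negative instantaneous rates are rectified
#' at zero; the rectified mass fraction is tracked and an error is raised if
#' it exceeds `max_rectified`.
#'
#' Defaults are the package's reference study conditions: 600 neurons, 40
#' modes, stimuli \{25, 30, 35\} Hz around threshold 30 Hz, 400 ms trials;
#' baselines average ~20 Hz, and the tuning spread is set so that an 80-
#' neuron optimal readout with a 50 ms window reaches a JND of about 3 Hz.
#' The default mode structure is a positive "global gain" mode plus weaker
#' mixed-sign modes, strong enough to give mean pairwise spike-count
#' correlations of roughly 0.02 in 50 ms windows — the weak-but-nonzero
#' noise-correlation regime typical of cortex that the readout analysis
#' presumes.
#'
#' @param n_neurons population size.
#' @param n_modes number of latent modes.
#' @param stimuli tested stimulus values (Hz).
#' @param s0 threshold stimulus.
#' @param T trial duration, seconds.
#' @param baseline per-neuron baseline rates (Hz) at `s = s0`; drawn as
#'   `8 + Gamma(shape 3, scale 4)` when NULL.
#' @param b per-neuron tuning slopes (Hz per Hz); `Normal(0, 0.8)` when
#'   NULL.
#' @param lambda mode strengths (Hz); by default a dominant global mode
#'   plus a `m^(-1/2)` tail, scaled with `sqrt(n_neurons)` so per-neuron
#'   shared variance is size-invariant.
#' @param U neuron x mode orthonormal shape matrix; by default a positive
#'   global-gain shape plus random orthonormal shapes.
#' @param tau_z latent correlation time, seconds.
#' @param dt simulation time step, seconds.
#' @param max_rectified error threshold on the rectified rate-mass fraction.
#' @param seed seed for drawing the structural randomness (baselines,
#'   tunings, mode shapes).
#' @return an object of class `latent_mode_spec`.
#' @export
latent_mode_spec <- function(n_neurons = 600, n_modes = 40,
                             stimuli = c(25, 30, 35), s0 = 30, T = 0.4,
                             baseline = NULL, b = NULL, lambda = NULL,
                             U = NULL, tau_z = 0.02, dt = 0.002,
                             max_rectified = 0.05, seed = 1) {
  set.seed(stream_seed(seed, "latent-spec"))
  if (is.null(baseline)) baseline <- 8 + rgamma(n_neurons, shape = 3, scale = 4)
  ## clipped so every draw keeps rates nonnegative at the extreme stimuli
  if (is.null(b)) b <- pmin(pmax(rnorm(n_neurons, 0, 1.13), -1.5), 1.5)
  if (is.null(lambda)) {
    lambda <- if (n_modes > 0) {
      ## default structure: a tuning-aligned (information-limiting) mode,
      ## a positive global-gain mode, and a decaying tail of random modes.
      ## The information-limiting strength sets a percept-noise floor of
      ## about 4 Hz^2 at a 50 ms window (0.506 is the window-averaged
      ## variance of a unit OU process with tau = 20 ms over 50 ms).
      il <- sqrt(4 * sum(b^2) / 0.506)
      c(il, 3.9 * sqrt(n_neurons),
        1.25 * sqrt(n_neurons) *
          seq_len(max(n_modes - 2, 0))^(-0.5))[seq_len(n_modes)]
    } else numeric(0)
  }
  if (is.null(U)) {
    U <- if (n_modes > 0) {
      g <- abs(1 + 0.4 * rnorm(n_neurons))
      raw <- cbind(b, g, matrix(rnorm(n_neurons * max(n_modes - 2, 0)),
                                n_neurons))[, seq_len(n_modes), drop = FALSE]
      Q <- qr.Q(qr(raw))
      ## align the leading shapes with the tuning / gain directions
      if (ncol(Q) >= 1) Q[, 1] <- Q[, 1] * sign(sum(Q[, 1] * b))
      if (ncol(Q) >= 2) Q[, 2] <- Q[, 2] * sign(sum(Q[, 2] * g))
      Q
    } else matrix(0, n_neurons, 0)
  }
  stopifnot(length(baseline) == n_neurons, length(b) == n_neurons,
            length(lambda) == ncol(U), nrow(U) == n_neurons)
  worst_rate <- baseline + b * (ifelse(b > 0, min(stimuli), max(stimuli)) - s0)
  if (any(worst_rate < 0))
    stop("infeasible spec: negative mean rate for some neuron/stimulus")
  structure(list(n_neurons = n_neurons, n_modes = length(lambda),
                 stimuli = stimuli, s0 = s0, T = T, baseline = baseline,
                 b = b, lambda = lambda, U = U, tau_z = tau_z, dt = dt,
                 max_rectified = max_rectified),
            class = "latent_mode_spec")
}

## simulate one trial's spikes for a neuron subset; returns list(neuron, time)
## and the rectified-mass bookkeeping. `UL` = U * lambda (precomputed, full).
.latent_trial <- function(spec, s, neurons, UL) {
  nb <- ceiling(spec$T / spec$dt)
  ## OU latents, unit stationary variance
  if (spec$n_modes > 0) {
    a <- exp(-spec$dt / spec$tau_z)
    z <- matrix(0, spec$n_modes, nb)
    z[, 1] <- rnorm(spec$n_modes)
    if (nb > 1) {
      eps <- matrix(rnorm(spec$n_modes * (nb - 1), sd = sqrt(1 - a^2)),
                    spec$n_modes, nb - 1)
      for (t in 2:nb) z[, t] <- a * z[, t - 1] + eps[, t - 1]
    }
    shared <- UL[neurons, , drop = FALSE] %*% z
  } else shared <- matrix(0, length(neurons), nb)
  rate <- spec$baseline[neurons] + spec$b[neurons] * (s - spec$s0) + shared
  neg <- -sum(rate[rate < 0]); tot <- sum(pmax(rate, 0)) + neg
  rate[rate < 0] <- 0
  cnt <- matrix(rpois(length(rate), rate * spec$dt), nrow(rate), nb)
  nz <- which(cnt > 0, arr.ind = TRUE)
  reps <- cnt[nz]
  neuron <- rep(neurons[nz[, 1]], reps)
  bin0 <- rep((nz[, 2] - 1) * spec$dt, reps)
  time <- pmin(bin0 + runif(length(neuron)) * spec$dt, spec$T)
  list(neuron = neuron, time = time, neg = neg, tot = tot)
}

#' Simulate a latent-mode population recording
#'
#' Generates a [spike_dataset()] (without choices) from a
#' [latent_mode_spec()]: each trial draws fresh Ornstein-Uhlenbeck mode
#' activations and Poisson spikes given the resulting rates.
#'
#' @param spec a [latent_mode_spec()].
#' @param trials either an integer (trials per stimulus, balanced over
#'   `spec$stimuli`) or a data.frame with columns `trial`, `s` (and
#'   optionally `pool`).
#' @param neurons neuron ids to record (default: all).
#' @param seed RNG seed.
#' @return a [spike_dataset()] with `choice = NA`.
#' @export
simulate_latent_mode_population <- function(spec, trials, neurons = NULL,
                                            seed = 1) {
  stopifnot(inherits(spec, "latent_mode_spec"))
  if (is.null(neurons)) neurons <- seq_len(spec$n_neurons)
  if (is.numeric(trials) && length(trials) == 1L) {
    trials <- data.frame(trial = seq_len(trials * length(spec$stimuli)),
                         s = rep(spec$stimuli, each = trials))
  }
  if (is.null(trials$pool)) trials$pool <- "1"
  set.seed(stream_seed(seed, "latent-sim"))
  UL <- sweep(spec$U, 2, spec$lambda, "*")
  out_n <- vector("list", nrow(trials)); out_t <- out_n
  neg <- tot <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- .latent_trial(spec, trials$s[i], neurons, UL)
    out_n[[i]] <- tr$neuron; out_t[[i]] <- tr$time
    neg <- neg + tr$neg; tot <- tot + tr$tot
  }
  rect <- if (tot > 0) neg / tot else 0
  if (rect > spec$max_rectified)
    stop(sprintf("rectified rate mass %.1f%% exceeds the allowed %.1f%%",
                 100 * rect, 100 * spec$max_rectified))
  if (rect > 0.005)
    warning(sprintf("%.2f%% of rate mass rectified at zero", 100 * rect))
  spikes <- data.frame(
    trial = rep(trials$trial, lengths(out_n)),
    neuron = unlist(out_n, use.names = FALSE),
    time = unlist(out_t, use.names = FALSE))
  trials$choice <- NA_integer_
  ds <- spike_dataset(spikes, trials,
                      pools = stats::setNames(
                        rep(list(as.integer(neurons)),
                            length(unique(trials$pool))),
                        unique(trials$pool)),
                      T = spec$T, s0 = spec$s0, n_total = spec$n_neurons)
  attr(ds, "rectified_fraction") <- rect
  ds
}

## exact kernel-integrated activities from raw spike times
.rbar_from_spikes <- function(data, kernel, neurons, trial_ids = NULL) {
  tr <- if (is.null(trial_ids)) data$trials$trial else trial_ids
  sp <- data$spikes[data$spikes$neuron %in% neurons &
                      data$spikes$trial %in% tr, , drop = FALSE]
  out <- matrix(0, length(tr), length(neurons),
                dimnames = list(NULL, as.character(neurons)))
  if (nrow(sp)) {
    wgt <- .kernel_density(kernel, sp$time)
    ti <- match(sp$trial, tr); ni <- match(sp$neuron, neurons)
    keep <- wgt > 0
    if (any(keep)) {
      acc <- rowsum(wgt[keep],
                    group = (ni[keep] - 1L) * length(tr) + ti[keep])
      out[as.integer(rownames(acc))] <- acc
    }
  }
  out
}

#' Construct the ground-truth readout of a synthetic experiment
#'
#' Draws a fixed random ensemble of `K_star` neurons, fits its optimal
#' (regularized Fisher) readout on the calibration trials, calibrates the
#' offset for an unbiased percept (`E[s_hat] = E[s]`), and evaluates the
#' achieved JND on held-out calibration trials. The calibration dataset
#' must not be reused for the subsequent analysis.
#'
#' @param data calibration [spike_dataset()] (the ensemble's neurons must
#'   be recorded on every trial).
#' @param K_star true readout ensemble size.
#' @param w_star,t_R_star true temporal parameters, seconds.
#' @param sigma_d_star true decision-noise SD, stimulus units.
#' @param ensemble optional explicit neuron ids (drawn at random when NULL).
#' @param lambda ridge for the readout fit: `"auto"` (empirical Bayes via
#'   [choose_regularization()]) or a number.
#' @param holdout_frac fraction of calibration trials held out for the JND
#'   evaluation.
#' @param b_true optional true integrated tuning of the ensemble's neurons
#'   (available for synthetic populations). When given, the readout is
#'   rescaled to satisfy the model's unbiasedness assumption exactly
#'   (`sum(a * b_true) = 1`) rather than only in-sample, so the percept's
#'   mean slope is 1 on fresh data.
#' @param seed RNG seed.
#' @return an object of class `ground_truth`: ensemble, readout weights
#'   `a` (support = ensemble), offset `a0`, kernel, `sigma_d`, achieved
#'   JND `Z`.
#' @export
build_ground_truth <- function(data, K_star = 80, w_star = 0.05,
                               t_R_star = 0.1, sigma_d_star = 1,
                               ensemble = NULL, lambda = "auto",
                               holdout_frac = 0.5, b_true = NULL,
                               seed = 1) {
  stopifnot(inherits(data, "spike_dataset"))
  set.seed(stream_seed(seed, "ground-truth"))
  n_tr <- nrow(data$trials)
  if (n_tr < 2 * K_star)
    stop("calibration requires at least 2 * K_star trials")
  if (is.null(ensemble)) {
    if (K_star > length(data$neurons))
      stop("K_star exceeds the number of recorded neurons")
    ensemble <- sort(sample(data$neurons, K_star))
  }
  K_star <- length(ensemble)
  kernel <- temporal_kernel("square", w = w_star, t_R = t_R_star)
  ## stratified learn / holdout split
  ho <- unlist(lapply(split(seq_len(n_tr), data$trials$s), function(idx)
    sample(idx, round(length(idx) * holdout_frac))), use.names = FALSE)
  learn <- setdiff(seq_len(n_tr), ho)
  rb <- .rbar_from_spikes(data, kernel, ensemble)
  s <- data$trials$s
  fitm <- .moments_from_rbar(rb[learn, , drop = FALSE], s[learn])
  lam <- if (identical(lambda, "auto"))
    choose_regularization(fitm$Cbb, fitm$bbar, n_trials = length(learn),
                          sigma_s2 = fitm$sigma_s2)
  else lambda
  a <- as.numeric(optimal_readout(list(bbar = fitm$bbar, Cbb = fitm$Cbb,
                                       sigma_s2 = fitm$sigma_s2),
                                  lambda = lam))
  ## unbiased-percept calibration: rescale to unit mean slope, using the
  ## true tuning when known, else the held-out tuning estimate (unbiased,
  ## independent of the learning split)
  if (is.null(b_true))
    b_true <- .moments_from_rbar(rb[ho, , drop = FALSE], s[ho])$bbar
  stopifnot(length(b_true) == length(ensemble))
  slope <- sum(a * b_true)
  if (abs(slope) < 1e-10) stop("readout orthogonal to the true tuning")
  a <- a / slope
  a0 <- mean(s[learn]) - sum(colMeans(rb[learn, , drop = FALSE]) * a)
  ## achieved JND on held-out trials
  shat <- a0 + as.numeric(rb[ho, , drop = FALSE] %*% as.numeric(a))
  resid <- shat - ave(shat, s[ho])
  Z <- sqrt(sum(resid^2) / (length(ho) - length(unique(s[ho]))) +
              sigma_d_star^2)
  structure(list(ensemble = ensemble, K = K_star, kernel = kernel,
                 sigma_d = sigma_d_star, a = as.numeric(a), a0 = a0,
                 Z = Z, lambda = lam, s0 = data$s0),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground-truth readout: K* = %d, w* = %g ms, t_R* = %g ms, sigma_d* = %g\n",
              x$K, 1e3 * x$kernel$w, 1e3 * x$kernel$t_R, x$sigma_d))
  cat(sprintf("  achieved JND Z* = %.3g (held-out calibration trials)\n", x$Z))
  invisible(x)
}

## weighted tuning + pooled covariance + sigma_s2 from an rbar matrix
.moments_from_rbar <- function(rbar, s) {
  st <- sort(unique(s))
  ns <- vapply(st, function(v) sum(s == v), numeric(1))
  gm <- t(matrix(vapply(st, function(v)
    colMeans(rbar[s == v, , drop = FALSE]), numeric(ncol(rbar))),
    nrow = ncol(rbar)))                      # stimulus x neuron
  sbar <- sum(ns * st) / sum(ns)
  bbar <- colSums(ns * (st - sbar) * gm) / sum(ns * (st - sbar)^2)
  rc <- .center_by_stim(rbar, s)
  Cbb <- crossprod(rc) / attr(rc, "denom")
  list(bbar = as.numeric(bbar), Cbb = (Cbb + t(Cbb)) / 2,
       sigma_s2 = mean(s^2) - mean(s)^2, group_means = gm, stimuli = st,
       n_s = ns)
}

#' Generate choices from a ground-truth readout
#'
#' Applies the forward model trial by trial: kernel-integrated activities
#' of the true ensemble, linear percept, Gaussian decision noise,
#' threshold. All of the ensemble's neurons must be recorded on every
#' trial.
#'
#' @param data a [spike_dataset()].
#' @param truth a [build_ground_truth()] object.
#' @param seed RNG seed for the decision noise.
#' @return the dataset with `choice` filled in.
#' @export
generate_behavior <- function(data, truth, seed = 1) {
  stopifnot(inherits(data, "spike_dataset"), inherits(truth, "ground_truth"))
  miss <- setdiff(truth$ensemble, data$neurons)
  if (length(miss))
    stop("ground-truth neurons absent from dataset: ",
         paste(head(miss, 5), collapse = ", "))
  rb <- .rbar_from_spikes(data, truth$kernel, truth$ensemble)
  shat <- truth$a0 + as.numeric(rb %*% truth$a)
  set.seed(stream_seed(seed, "decision"))
  dm <- decision_model(s0 = truth$s0, mu_d = 0, sigma_d = truth$sigma_d)
  data$trials$choice <- draw_choice(shat, dm)
  data
}

#' Split a fully recorded dataset into recording pools
#'
#' Emulates an experiment that observes the population through pools of
#' simultaneously recorded neurons: trials are partitioned into disjoint
#' blocks (stratified by stimulus), each block is assigned a random
#' neuron set of size `pool_size`, and spikes from neurons outside a
#' trial's pool are removed. Pools may overlap in neurons; trials never
#' overlap.
#'
#' @param data a [spike_dataset()] recording all its neurons on all trials.
#' @param n_pools number of pools.
#' @param pool_size neurons per pool.
#' @param seed RNG seed.
#' @return a pooled [spike_dataset()].
#' @export
split_recording_pools <- function(data, n_pools, pool_size, seed = 1) {
  stopifnot(inherits(data, "spike_dataset"))
  if (pool_size > length(data$neurons))
    stop("pool_size exceeds the number of recorded neurons")
  set.seed(stream_seed(seed, "pools"))
  n_tr <- nrow(data$trials)
  if (n_pools > n_tr) stop("more pools than trials")
  ## stratified-by-stimulus disjoint trial blocks
  assign <- integer(n_tr)
  for (idx in split(seq_len(n_tr), data$trials$s)) {
    sh <- sample(idx)
    assign[sh] <- rep_len(seq_len(n_pools), length(sh))
  }
  pools <- lapply(seq_len(n_pools), function(p)
    sort(sample(data$neurons, pool_size)))
  names(pools) <- as.character(seq_len(n_pools))
  trials <- data$trials
  trials$pool <- as.character(assign)
  pool_of <- stats::setNames(trials$pool, trials$trial)
  sp <- data$spikes
  sp_pool <- pool_of[as.character(sp$trial)]
  keep <- logical(nrow(sp))
  for (p in names(pools)) {
    sel <- sp_pool == p
    keep[sel] <- sp$neuron[sel] %in% pools[[p]]
  }
  spike_dataset(sp[keep, , drop = FALSE], trials, pools = pools,
                T = data$T, s0 = data$s0, n_total = data$n_total)
}

#' Simulate a complete validation experiment
#'
#' The package's reference synthetic experiment: a latent-mode population,
#' a hidden optimal readout with the stated true parameters, choices from
#' the forward model, and observation through pools of simultaneously
#' recorded neurons. Calibration trials (used to learn the readout) are
#' generated separately and never enter the returned analysis dataset.
#' Only the neurons needed per trial (its pool plus the true ensemble) are
#' simulated, so the cost scales with the recorded — not total — population.
#'
#' @param spec a [latent_mode_spec()].
#' @param K_star,w_star,t_R_star,sigma_d_star true readout parameters.
#' @param n_pools,pool_size,trials_per_stim recording design (per pool).
#' @param n_calibration_per_stim calibration trials per stimulus; the
#'   default is large enough that the learned hidden readout is close to
#'   the truly optimal one, as the reference construction requires.
#' @param seed master seed; all stages derive named streams from it.
#' @return list with `data` (pooled [spike_dataset()] with choices) and
#'   `truth` (a `ground_truth`).
#' @export
simulate_experiment <- function(spec = latent_mode_spec(),
                                K_star = 80, w_star = 0.05, t_R_star = 0.1,
                                sigma_d_star = 1, n_pools = 4,
                                pool_size = 120, trials_per_stim = 180,
                                n_calibration_per_stim = 1000, seed = 1) {
  stopifnot(inherits(spec, "latent_mode_spec"))
  set.seed(stream_seed(seed, "ensemble"))
  ensemble <- sort(sample(spec$n_neurons, K_star))
  ## calibration: record only the true ensemble
  cal <- simulate_latent_mode_population(
    spec, trials = n_calibration_per_stim, neurons = ensemble,
    seed = stream_seed(seed, "calibration"))
  truth <- build_ground_truth(cal, K_star = K_star, w_star = w_star,
                              t_R_star = t_R_star,
                              sigma_d_star = sigma_d_star,
                              ensemble = ensemble,
                              seed = stream_seed(seed, "truth-fit"))
  ## analysis: pools of simultaneously recorded neurons
  set.seed(stream_seed(seed, "pools"))
  pools <- lapply(seq_len(n_pools), function(p)
    sort(sample(spec$n_neurons, pool_size)))
  names(pools) <- as.character(seq_len(n_pools))
  n_per_pool <- trials_per_stim * length(spec$stimuli)
  trials <- data.frame(
    trial = seq_len(n_pools * n_per_pool),
    s = rep(rep(spec$stimuli, each = trials_per_stim), n_pools),
    pool = as.character(rep(seq_len(n_pools), each = n_per_pool)))
  kernel <- truth$kernel
  UL <- sweep(spec$U, 2, spec$lambda, "*")
  set.seed(stream_seed(seed, "analysis-sim"))
  xi <- rnorm(nrow(trials), 0, sigma_d_star)
  out_n <- vector("list", nrow(trials)); out_t <- out_n
  choice <- integer(nrow(trials))
  neg <- tot <- 0
  a_full <- stats::setNames(truth$a, as.character(ensemble))
  for (i in seq_len(nrow(trials))) {
    pn <- pools[[trials$pool[i]]]
    un <- sort(unique(c(pn, ensemble)))
    tr <- .latent_trial(spec, trials$s[i], un, UL)
    neg <- neg + tr$neg; tot <- tot + tr$tot
    in_E <- tr$neuron %in% ensemble
    rbar <- numeric(length(ensemble))
    if (any(in_E)) {
      w <- .kernel_density(kernel, tr$time[in_E])
      acc <- rowsum(w, match(tr$neuron[in_E], ensemble))
      rbar[as.integer(rownames(acc))] <- acc
    }
    shat <- truth$a0 + sum(truth$a * rbar)
    choice[i] <- as.integer(shat + xi[i] - spec$s0 > 0)
    in_pool <- tr$neuron %in% pn
    out_n[[i]] <- tr$neuron[in_pool]
    out_t[[i]] <- tr$time[in_pool]
  }
  rect <- if (tot > 0) neg / tot else 0
  if (rect > spec$max_rectified)
    stop(sprintf("rectified rate mass %.1f%% exceeds the allowed %.1f%%",
                 100 * rect, 100 * spec$max_rectified))
  trials$choice <- choice
  spikes <- data.frame(trial = rep(trials$trial, lengths(out_n)),
                       neuron = unlist(out_n, use.names = FALSE),
                       time = unlist(out_t, use.names = FALSE))
  data <- spike_dataset(spikes, trials, pools = pools, T = spec$T,
                        s0 = spec$s0, n_total = spec$n_neurons)
  list(data = data, truth = truth)
}
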