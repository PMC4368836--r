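#' Specification of the recurrent LIF validation network
#'
#' A stimulus-encoding recurrent network of leaky integrate-and-fire
#' neurons: Poisson input units fire at the stimulus rate s (Hz); one group
#' of encoding neurons receives sparse excitatory input projections
#' (positive tuning), another sparse inhibitory projections (negative
#' tuning), the rest none; all encoding neurons are recurrently coupled
#' with sparse, balanced random weights and random conduction delays.
#' Membrane potentials are normalized (threshold 1, reset 0).
#'
#' @param n_inputs Poisson input units.
#' @param n_neurons encoding LIF neurons.
#' @param n_exc_input,n_inh_input neurons receiving excitatory /
#'   inhibitory input projections (the remainder receive none).
#' @param p_input connection probability input -> target.
#' @param p_connect recurrent connection probability.
#' @param w_input input synaptic weight (potential units per spike).
#' @param w_scale SD of the zero-mean recurrent weights.
#' @param delay_max maximum recurrent conduction delay, seconds.
#' @param tau_m membrane time constant, seconds.
#' @param t_ref absolute refractory period, seconds.
#' @param T trial duration, seconds.
#' @param dt integration step, seconds.
#' @param noise_sd SD of the white membrane noise (potential units per
#'   sqrt(second)), the diffusion approximation of unspecific background
#'   input; keeps firing fluctuation-driven and irregular.
#' @param rate_ceiling mean population rate (Hz) above which the
#'   simulation aborts with an error (runaway excitation).
#' @return an object of class `lif_network_spec`.
#' @export
lif_network_spec <- function(n_inputs = 200, n_neurons = 400,
                             n_exc_input = 80, n_inh_input = 80,
                             p_input = 0.4, p_connect = 0.02,
                             w_input = 0.008, w_scale = 0.02,
                             delay_max = 0.005, tau_m = 0.02,
                             t_ref = 0.002, T = 0.4, dt = 0.0005,
                             noise_sd = 2.5, rate_ceiling = 200) {
  stopifnot(n_exc_input + n_inh_input <= n_neurons, delay_max >= 0)
  structure(as.list(environment()), class = "lif_network_spec")
}

#' Simulate the recurrent LIF network
#'
#' Euler integration of the network defined by [lif_network_spec()], one
#' trial per row of the trial table. A constant bias current keeps neurons
#' near threshold so that unconnected neurons fire at a low baseline; input
#' and recurrent spikes arrive as delta-function potential kicks, recurrent
#' ones after their (fixed, random) conduction delay.
#'
#' @param spec a [lif_network_spec()].
#' @param trials integer (trials per stimulus) or data.frame with columns
#'   `trial`, `s`.
#' @param stimuli stimulus values (input rates in Hz) used when `trials`
#'   is a count.
#' @param s0 task threshold recorded in the dataset.
#' @param bias constant depolarizing drive (potential units per second);
#'   the default holds neurons slightly below threshold, so that firing is
#'   driven by input and membrane-noise fluctuations (irregular spiking)
#'   while inhibitory input still produces negative tuning.
#' @param seed RNG seed (connectivity and trial noise derive named
#'   streams from it).
#' @return a [spike_dataset()] without choices; attribute `mean_rate`
#'   holds the grand-average firing rate in Hz.
#' @export
simulate_lif_network <- function(spec, trials, stimuli = c(25, 30, 35),
                                 s0 = 30, bias = 40, seed = 1) {
  stopifnot(inherits(spec, "lif_network_spec"))
  if (is.numeric(trials) && length(trials) == 1L)
    trials <- data.frame(trial = seq_len(trials * length(stimuli)),
                         s = rep(stimuli, each = trials))
  N <- spec$n_neurons
  set.seed(stream_seed(seed, "lif-wiring"))
  ## input projections: sparse 0/1 masks scaled by +-w_input
  tgt_exc <- seq_len(spec$n_exc_input)
  tgt_inh <- spec$n_exc_input + seq_len(spec$n_inh_input)
  Win <- matrix(0, spec$n_inputs, N)
  Win[, tgt_exc] <- spec$w_input *
    (matrix(runif(spec$n_inputs * length(tgt_exc)), spec$n_inputs) < spec$p_input)
  Win[, tgt_inh] <- -spec$w_input *
    (matrix(runif(spec$n_inputs * length(tgt_inh)), spec$n_inputs) < spec$p_input)
  ## recurrent edge list with per-edge delays (in steps)
  mask <- which(matrix(runif(N * N), N) < spec$p_connect & diag(N) == 0)
  pre <- (mask - 1L) %% N + 1L
  post <- (mask - 1L) %/% N + 1L
  wrec <- rnorm(length(pre), 0, spec$w_scale)
  wrec <- wrec - mean(wrec)                     # balanced
  dstep <- sample.int(max(1L, round(spec$delay_max / spec$dt)),
                      length(pre), replace = TRUE)
  edges_by_pre <- split(seq_along(pre), pre)
  nb <- ceiling(spec$T / spec$dt)
  dmax <- max(dstep)
  leak <- exp(-spec$dt / spec$tau_m)
  noise_step <- spec$noise_sd * sqrt(spec$dt)
  ref_steps <- max(1L, round(spec$t_ref / spec$dt))
  set.seed(stream_seed(seed, "lif-trials"))
  out_n <- vector("list", nrow(trials)); out_t <- out_n
  total_spikes <- 0
  for (i in seq_len(nrow(trials))) {
    s <- trials$s[i]
    V <- runif(N)                                # random initial potentials
    refr <- integer(N)
    buf <- matrix(0, dmax + 1L, N)               # ring buffer of future input
    sp_n <- integer(0); sp_b <- integer(0)
    for (t in seq_len(nb)) {
      row <- (t - 1L) %% (dmax + 1L) + 1L
      inp_cnt <- rpois(spec$n_inputs, s * spec$dt)
      drive <- as.numeric(crossprod(Win, inp_cnt)) + buf[row, ] +
        bias * spec$dt
      buf[row, ] <- 0
      active <- refr <= 0L
      V[active] <- V[active] * leak + drive[active] +
        rnorm(sum(active), 0, noise_step)
      refr[!active] <- refr[!active] - 1L
      fired <- which(active & V >= 1)
      if (length(fired)) {
        V[fired] <- 0
        refr[fired] <- ref_steps
        sp_n <- c(sp_n, fired); sp_b <- c(sp_b, rep.int(t, length(fired)))
        for (f in fired) {
          ed <- edges_by_pre[[as.character(f)]]
          if (!is.null(ed)) {
            rows <- (t + dstep[ed] - 1L) %% (dmax + 1L) + 1L
            for (k in seq_along(ed))
              buf[rows[k], post[ed[k]]] <- buf[rows[k], post[ed[k]]] + wrec[ed[k]]
          }
        }
      }
    }
    total_spikes <- total_spikes + length(sp_n)
    rate_now <- total_spikes / (i * N * spec$T)
    if (rate_now > spec$rate_ceiling)
      stop("runaway network activity (mean rate ", round(rate_now),
           " Hz); rescale 'w_scale' / 'w_input' downwards")
    out_n[[i]] <- sp_n
    out_t[[i]] <- pmin((sp_b - runif(length(sp_b))) * spec$dt, spec$T)
  }
  trials$choice <- NA_integer_
  trials$pool <- "1"
  spikes <- data.frame(trial = rep(trials$trial, lengths(out_n)),
                       neuron = unlist(out_n, use.names = FALSE),
                       time = unlist(out_t, use.names = FALSE))
  ds <- spike_dataset(spikes, trials,
                      pools = list("1" = seq_len(N)),
                      T = spec$T, s0 = s0, n_total = N)
  attr(ds, "mean_rate") <- total_spikes / (nrow(trials) * N * spec$T)
  attr(ds, "groups") <- list(exc_input = tgt_exc, inh_input = tgt_inh)
  ds
}
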