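#' Linear readout model
#'
#' A perceptual policy: the percept is \eqn{\hat s = a_0 + \sum_i a_i \bar
#' r_i}, where the weights `a` have support on the readout ensemble (the K
#' neurons with nonzero entries) and \eqn{\bar r} are the kernel-integrated
#' activities. Weights are in stimulus units per rate unit.
#'
#' @param a named or plain numeric vector of readout weights, one per neuron
#'   of the population it is defined over. Zero entries mark neurons outside
#'   the readout ensemble.
#' @param a0 offset, stimulus units.
#' @param kernel the [temporal_kernel()] used to form \eqn{\bar r}.
#' @param neurons optional integer ids the entries of `a` refer to
#'   (defaults to `seq_along(a)`).
#' @return an object of class `readout_model`.
#' @export
readout_model <- function(a, a0 = 0, kernel, neurons = seq_along(a)) {
  stopifnot(is.numeric(a), is.numeric(a0), length(a0) == 1L,
            inherits(kernel, "temporal_kernel"), length(neurons) == length(a))
  structure(list(a = as.numeric(a), a0 = a0, kernel = kernel,
                 neurons = as.integer(neurons)),
            class = "readout_model")
}

#' @export
print.readout_model <- function(x, ...) {
  K <- sum(x$a != 0)
  cat(sprintf("linear readout: K = %d of %d neurons, a0 = %.4g, %s kernel (w = %g ms, t_R = %g ms)\n",
              K, length(x$a), x$a0, x$kernel$shape,
              1e3 * x$kernel$w, 1e3 * x$kernel$t_R))
  invisible(x)
}

#' @export
coef.readout_model <- function(object, ...) {
  structure(object$a, names = object$neurons)
}

#' Ensemble (support) of a readout model
#' @param model a [readout_model()].
#' @return integer neuron ids with nonzero weight.
#' @export
readout_ensemble <- function(model) {
  stopifnot(inherits(model, "readout_model"))
  model$neurons[model$a != 0]
}

#' Decision model of the 2AFC task
#'
#' The binary choice is \eqn{c = H(\hat s + \xi_d - s_0)} with decision noise
#' \eqn{\xi_d \sim N(\mu_d, \sigma_d^2)}: the percept, corrupted by
#' extra-sensory Gaussian noise, is compared against the task threshold
#' `s0`. For `sigma_d = 0` the threshold is deterministic.
#'
#' @param s0 threshold stimulus, stimulus units.
#' @param mu_d decision bias, stimulus units.
#' @param sigma_d decision-noise standard deviation, stimulus units, >= 0.
#' @return an object of class `decision_model`.
#' @export
decision_model <- function(s0, mu_d = 0, sigma_d = 0) {
  stopifnot(is.numeric(s0), is.numeric(mu_d), is.numeric(sigma_d),
            length(sigma_d) == 1L)
  if (sigma_d < 0) stop("'sigma_d' must be >= 0")
  structure(list(s0 = s0, mu_d = mu_d, sigma_d = sigma_d),
            class = "decision_model")
}

#' @export
print.decision_model <- function(x, ...) {
  cat(sprintf("decision model: s0 = %g, mu_d = %g, sigma_d = %g (stimulus units)\n",
              x$s0, x$mu_d, x$sigma_d))
  invisible(x)
}

#' Percept from integrated activities
#'
#' \eqn{\hat s = a_0 + \sum_i a_i \bar r_i}. `rbar` must cover every neuron
#' in the support of the readout; it may be a named vector keyed by neuron
#' id, or a plain vector aligned with `model$neurons`.
#'
#' @param rbar integrated activities, rate units.
#' @param model a [readout_model()].
#' @return the percept \eqn{\hat s}, stimulus units.
#' @export
compute_percept <- function(rbar, model) {
  stopifnot(inherits(model, "readout_model"))
  sup <- readout_ensemble(model)
  if (!is.null(names(rbar))) {
    miss <- setdiff(as.character(sup), names(rbar))
    if (length(miss))
      stop("'rbar' is missing readout neurons: ", paste(miss, collapse = ", "))
    r <- rbar[as.character(model$neurons)]
    r[is.na(r)] <- 0
  } else {
    if (length(rbar) != length(model$a))
      stop("'rbar' must cover all neurons of the readout model")
    r <- rbar
  }
  model$a0 + sum(model$a * r)
}

#' Draw a binary choice from a percept
#'
#' \eqn{c = H(\hat s + \xi_d - s_0)}, so that for `sigma_d > 0`
#' \eqn{P(c = 1 \mid \hat s) = \Phi((\hat s + \mu_d - s_0)/\sigma_d)}.
#' Vectorized over `shat`; uses R's global RNG stream.
#'
#' @param shat percept value(s), stimulus units.
#' @param decision a [decision_model()].
#' @return integer choice(s) in \{0, 1\}.
#' @export
draw_choice <- function(shat, decision) {
  stopifnot(inherits(decision, "decision_model"))
  n <- length(shat)
  xi <- if (decision$sigma_d > 0)
    rnorm(n, decision$mu_d, decision$sigma_d) else rep(decision$mu_d, n)
  as.integer(shat + xi - decision$s0 > 0)
}
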