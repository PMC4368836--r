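#' Choice-covariance scaling factor kappa(Z)
#'
#' \eqn{\kappa(Z) = E_s[\,\mathcal G(s;\, s_0 - \mu_d,\, Z)\,]}: the normal
#' density at each tested stimulus, centred on the effective threshold and
#' with SD equal to the JND, averaged over the stimulus distribution. It
#' converts percept covariances into choice covariances and is nearly
#' constant in Z when the tested stimuli span a range comparable to Z.
#'
#' @param Z just-noticeable difference, > 0.
#' @param stimuli tested stimulus values.
#' @param prob probabilities of the stimuli (default uniform; trial counts
#'   are accepted and normalized).
#' @param mu_d decision bias.
#' @param s0 threshold stimulus.
#' @return kappa, in 1/stimulus units.
#' @export
kappa <- function(Z, stimuli, prob = NULL, mu_d = 0, s0 = 0) {
  if (!is.numeric(Z) || any(Z <= 0)) stop("'Z' must be > 0")
  if (is.null(prob)) prob <- rep(1, length(stimuli))
  prob <- prob / sum(prob)
  vapply(Z, function(z) sum(prob * dnorm(stimuli, s0 - mu_d, z)), numeric(1))
}

#' Predicted percept moments of a readout
#'
#' The characteristic equations of the linear readout: the slope of the
#' mean percept in the stimulus, \eqn{\bar b^\top a}; the percept variance,
#' \eqn{a^\top \bar{\bar C} a}; and the percept-covariance curves
#' \eqn{\bar C(t) a}.
#'
#' @param a readout weight vector over the neurons of `istats`.
#' @param istats an `integrated_stats` object.
#' @return list with `slope`, `variance`, `cov_t` (neuron x bin matrix).
#' @export
predict_moments <- function(a, istats) {
  stopifnot(inherits(istats, "integrated_stats"))
  if (length(a) != length(istats$bbar))
    stop("'a' must have one weight per neuron of 'istats'")
  nn <- length(a); B <- dim(istats$Cbar)[3]
  cov_t <- matrix(matrix(aperm(istats$Cbar, c(1, 3, 2)), nrow = nn * B) %*% a,
                  nn, B)
  list(slope = sum(istats$bbar * a),
       variance = as.numeric(crossprod(a, istats$Cbb %*% a)),
       cov_t = cov_t)
}

## ridge / pseudoinverse solve of (C + lambda I) x = b
.reg_solve <- function(C, b, lambda = 0, sigma_s2 = 1) {
  K <- length(b)
  M <- C + diag(lambda, K)
  x <- tryCatch(solve(M, b), error = function(e) NULL)
  if (is.null(x) || !all(is.finite(x))) {
    ## singular noise covariance: total-covariance form with pseudoinverse
    A <- C + sigma_s2 * tcrossprod(b)
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    keep <- e$values > max(e$values, 0) * K * .Machine$double.eps
    if (!any(keep)) stop("covariance matrix is numerically zero")
    x <- e$vectors[, keep, drop = FALSE] %*%
      ((crossprod(e$vectors[, keep, drop = FALSE], b)) / e$values[keep])
    x <- as.numeric(x)
    ## A^+ b is proportional to C^+ b within the span; the normalization
    ## below removes the proportionality constant
  }
  x
}

#' Optimal (Fisher-discriminant) readout restricted to an ensemble
#'
#' The minimum-variance unbiased linear readout over the given neurons:
#' \eqn{a_r = (\bar{\bar C}_r + \lambda I)^{-1} \bar b_r / [\bar b_r^\top
#' (\bar{\bar C}_r + \lambda I)^{-1} \bar b_r]}. With `lambda = 0` and a
#' singular covariance, the total-covariance form with a Moore-Penrose
#' pseudoinverse is used. The result satisfies \eqn{\bar b_r^\top a_r = 1}
#' (unbiased percept) when `lambda = 0`.
#'
#' @param istats an `integrated_stats` object, or a list with elements
#'   `bbar`, `Cbb` (and optionally `sigma_s2`).
#' @param ensemble optional indices (into the neurons of `istats`)
#'   restricting the readout support; default all.
#' @param lambda ridge regularization, >= 0.
#' @return numeric weight vector over all neurons of `istats` (zero outside
#'   `ensemble`), with attribute `"S"` holding the predicted percept noise
#'   variance \eqn{(\bar b_r^\top (\bar{\bar C}_r + \lambda I)^{-1} \bar
#'   b_r)^{-1}}.
#' @export
optimal_readout <- function(istats, ensemble = NULL, lambda = 0) {
  bbar <- istats$bbar; Cbb <- istats$Cbb
  sigma_s2 <- if (!is.null(istats$sigma_s2)) istats$sigma_s2 else 1
  if (lambda < 0) stop("'lambda' must be >= 0")
  N <- length(bbar)
  if (is.null(ensemble)) ensemble <- seq_len(N)
  br <- bbar[ensemble]
  if (all(br == 0)) stop("restricted tuning vector is zero: readout undefined")
  Cr <- Cbb[ensemble, ensemble, drop = FALSE]
  x <- .reg_solve(Cr, br, lambda, sigma_s2)
  btx <- sum(br * x)
  if (btx <= 0) stop("non-positive discriminant norm; covariance not PSD?")
  a <- numeric(N)
  a[ensemble] <- x / btx
  attr(a, "S") <- 1 / btx
  a
}

#' Predicted just-noticeable difference of a restricted optimal readout
#'
#' \eqn{Z^2 = [\bar b_r^\top (\bar{\bar C}_r + \lambda I)^{-1} \bar
#' b_r]^{-1} + \sigma_d^2}; `lambda = 0` gives the unregularized formula.
#'
#' @inheritParams optimal_readout
#' @param sigma_d decision-noise SD.
#' @return predicted Z (stimulus units).
#' @export
predict_jnd <- function(istats, ensemble = NULL, sigma_d = 0, lambda = 0) {
  a <- optimal_readout(istats, ensemble, lambda)
  sqrt(attr(a, "S") + sigma_d^2)
}

#' Predicted choice-covariance curves of a restricted optimal readout
#'
#' For a candidate ensemble with optimal readout, the model predicts the CC
#' curve of *every* simultaneously recorded neuron:
#' \eqn{d_i(t) = \kappa(Z)(Z^2 - \sigma_d^2)\, \bar C_{ir}(t) (\bar{\bar
#' C}_r + \lambda I)^{-1} \bar b_r}. For neurons inside the ensemble the
#' integrated form collapses to a pure proportionality to tuning,
#' \eqn{\bar d_i = \kappa(Z)(Z^2 - \sigma_d^2)\, \bar b_i}.
#'
#' @inheritParams predict_jnd
#' @param kappa_val the scaling factor \eqn{\kappa}; see [kappa()]. In the
#'   inference this is evaluated at the *measured* JND.
#' @return list with `d` (neuron x bin predicted CC curves), `dbar`
#'   (integrated), `Z` (predicted JND), `a` (readout weights).
#' @export
predict_cc <- function(istats, ensemble = NULL, sigma_d = 0, lambda = 0,
                       kappa_val = 1) {
  stopifnot(inherits(istats, "integrated_stats") ||
              (!is.null(istats$Cbar) && !is.null(istats$bbar)))
  a <- optimal_readout(istats, ensemble, lambda)
  S <- attr(a, "S")
  Z <- sqrt(S + sigma_d^2)
  ## (Z^2 - sigma_d^2) (Cbb_r + lambda I)^{-1} bbar_r equals a restricted to
  ## the ensemble, so the prediction is simply kappa * Cbar(t) a (resp.
  ## kappa * Cbb a for the integrated form, the d = kappa Cbb a relation).
  pm <- predict_moments(as.numeric(a), istats)
  d <- kappa_val * pm$cov_t
  dbar <- as.numeric(kappa_val * (istats$Cbb %*% as.numeric(a)))
  list(d = d, dbar = dbar, Z = Z, a = as.numeric(a), S = S)
}

#' Tuning-CC cross indicator q(u, t)
#'
#' \eqn{q(u, t) = \langle b_i(u)\, d_i(t) \rangle_i}: the population-average
#' product of tuning at time u and choice covariance at time t. Its double
#' kernel integral \eqn{\bar{\bar q} = \langle \bar b_i \bar d_i \rangle_i}
#' is the best regression coefficient predicting a neuron's integrated CC
#' from its tuning.
#'
#' @param b neuron x bin tuning matrix.
#' @param d neuron x bin CC matrix (same neurons and grid).
#' @param kernel optional [temporal_kernel()]; when given, `qbb` is
#'   computed by double quadrature.
#' @param breaks bin edges matching the columns of `b` and `d` (required
#'   with `kernel`).
#' @return list with `q` (bin x bin matrix, rows = u, cols = t) and `qbb`
#'   (scalar or NULL).
#' @export
indicator_q <- function(b, d, kernel = NULL, breaks = NULL) {
  b <- as.matrix(b); d <- as.matrix(d)
  if (!nrow(b)) stop("empty neuron set")
  stopifnot(identical(dim(b), dim(d)))
  q <- crossprod(b, d) / nrow(b)
  qbb <- NULL
  if (!is.null(kernel)) {
    if (is.null(breaks)) stop("'breaks' needed to integrate q")
    kw <- kernel_weights(kernel, breaks)
    qbb <- as.numeric(crossprod(kw, q %*% kw))
  }
  list(q = q, qbb = qbb)
}

#' Deviation-from-proportionality indicator V
#'
#' \eqn{V = \langle \bar b_i^2 \rangle \langle \bar d_i^2 \rangle -
#' \bar{\bar q}^2}. V is zero exactly when the integrated CC is proportional
#' to the integrated tuning over the averaged population (the signature of a
#' globally optimal readout), and positive otherwise (Cauchy-Schwarz).
#'
#' @param bbar integrated tuning per neuron.
#' @param dbar integrated CC per neuron.
#' @param qbb optionally a precomputed \eqn{\bar{\bar q}}; defaults to
#'   `mean(bbar * dbar)`.
#' @return V (scalar).
#' @export
indicator_V <- function(bbar, dbar, qbb = NULL) {
  stopifnot(length(bbar) == length(dbar), length(bbar) > 0)
  if (is.null(qbb)) qbb <- mean(bbar * dbar)
  mean(bbar^2) * mean(dbar^2) - qbb^2
}

#' Mix within-ensemble and out-of-ensemble indicator components
#'
#' Population-level indicators are convex combinations of the
#' within-ensemble and out-of-ensemble averages with weight
#' \eqn{p = K/N_{tot}}: a neuron sampled at random from the population lies
#' in the readout ensemble with probability p.
#'
#' @param x_in within-ensemble component (scalar, vector or matrix).
#' @param x_out out-of-ensemble component (same shape).
#' @param K ensemble size.
#' @param n_total full population size, >= K.
#' @return the mixed component.
#' @export
mix_in_out <- function(x_in, x_out, K, n_total) {
  if (K <= 0 || K > n_total) stop("'K' must satisfy 0 < K <= n_total")
  p <- K / n_total
  p * x_in + (1 - p) * x_out
}
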