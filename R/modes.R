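#' SVD mode decomposition of time-averaged population activity
#'
#' Decomposes the trial x neuron matrix of integrated activities \eqn{\bar
#' r} into population *modes*: \eqn{\bar r_i^{sq} = \bar r_i^0 + \sum_m
#' \lambda_m u_i^m v_m^{sq}}, with orthonormal mode shapes (columns of U),
#' strengths \eqn{\lambda_m > 0} in descending order, and activations v
#' scaled to unit across-trial second moment (so that the total covariance
#' of \eqn{\bar r} is \eqn{U \Lambda^2 U^\top}). The number of modes M is
#' the numerical rank of the centred matrix.
#'
#' @param rbar numeric matrix, trials x neurons (>= 2 trials).
#' @param tol rank tolerance relative to the largest singular value
#'   (default: standard rank-revealing cutoff).
#' @return an object of class `mode_decomp`: `M`, `lambda` (length M), `U`
#'   (neuron x M), `v` (trial x M, Cov[v] = Id), `r0` (per-neuron grand
#'   mean), `n_trials`, `n_neurons`.
#' @export
svd_modes <- function(rbar, tol = NULL) {
  rbar <- as.matrix(rbar)
  n <- nrow(rbar); N <- ncol(rbar)
  if (n < 2L) stop("mode decomposition requires >= 2 trials")
  r0 <- colMeans(rbar)
  Xc <- sweep(rbar, 2, r0)
  sv <- svd(Xc)
  if (is.null(tol)) tol <- max(dim(Xc)) * .Machine$double.eps
  keep <- sv$d > tol * max(sv$d, 0)
  M <- sum(keep)
  if (M == 0L)
    return(structure(list(M = 0L, lambda = numeric(0),
                          U = matrix(0, N, 0), v = matrix(0, n, 0), r0 = r0,
                          n_trials = n, n_neurons = N),
                     class = "mode_decomp"))
  structure(list(M = M,
                 lambda = sv$d[keep] / sqrt(n),
                 U = sv$v[, keep, drop = FALSE],
                 v = sqrt(n) * sv$u[, keep, drop = FALSE],
                 r0 = r0, n_trials = n, n_neurons = N),
            class = "mode_decomp")
}

#' @export
print.mode_decomp <- function(x, ...) {
  cat(sprintf("mode decomposition: %d modes from %d neurons x %d trials\n",
              x$M, x$n_neurons, x$n_trials))
  if (x$M) cat("  lambda:", paste(sprintf("%.3g", head(x$lambda, 8)),
                                  collapse = " "),
               if (x$M > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
plot.mode_decomp <- function(x, ...) {
  plot(seq_len(x$M), x$lambda^2, log = "y", xlab = "mode",
       ylab = expression(lambda[m]^2), pch = 16, ...)
  invisible(x)
}

#' Mode tuning and mode sensitivities
#'
#' Regresses each mode's activation on the stimulus to get the mode tuning
#' \eqn{\eta_m} (per stimulus unit) and the mode sensitivities \eqn{y_m =
#' \sigma_s^2 \eta_m^2 \in [0, 1]}. The tuning is cross-checked against the
#' algebraic route \eqn{\bar b = U \Lambda \eta} when a tuning vector is
#' supplied; the full-population optimal sensitivity is \eqn{Y^{tot} =
#' \sum_m y_m}.
#'
#' @param decomp a [svd_modes()] decomposition.
#' @param s stimulus value per trial (length `n_trials`).
#' @param bbar optional integrated tuning vector (length `n_neurons`) for
#'   the algebraic cross-check route.
#' @return list with `eta`, `y`, `Y_tot`, `sigma_s2` and, when `bbar` is
#'   given, `eta_b` (the \eqn{\Lambda^{-1} U^\top \bar b} route).
#' @export
mode_tuning <- function(decomp, s, bbar = NULL) {
  stopifnot(inherits(decomp, "mode_decomp"), length(s) == decomp$n_trials)
  if (length(unique(s)) < 2L) stop("mode tuning requires >= 2 stimuli")
  sc <- s - mean(s)
  sigma_s2 <- mean(sc^2)
  ## Cov[v_m, s] / Var[s], population (1/n) convention matching Cov[v] = Id
  eta <- as.numeric(crossprod(decomp$v, sc)) / (decomp$n_trials * sigma_s2)
  y <- sigma_s2 * eta^2
  out <- list(eta = eta, y = y, Y_tot = sum(y), sigma_s2 = sigma_s2)
  if (!is.null(bbar)) {
    out$eta_b <- as.numeric(crossprod(decomp$U, bbar)) / decomp$lambda
  }
  out
}

## projector of an ensemble in mode space: P = X (X^T X)^+ X^T,
## X = Lambda U^T H^T  (M x K)
.mode_projector <- function(decomp, ensemble) {
  X <- decomp$lambda * t(decomp$U[ensemble, , drop = FALSE])
  sv <- svd(X, nv = 0)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  W <- sv$u[, keep, drop = FALSE]
  tcrossprod(W)
}

#' Mode observation fractions
#'
#' For each ensemble size K, the average orthogonal projector (in mode
#' space) onto the span of K randomly sampled neurons' activity vectors;
#' its diagonal \eqn{\epsilon_m(K)} measures to what extent mode m is
#' observed in random K-neuron sub-ensembles. Each sampled projector has
#' trace equal to its rank, so \eqn{\sum_m \epsilon_m(K) = K} whenever
#' K <= M and samples are in general position; \eqn{\epsilon_m(N_{tot}) =
#' 1} for all modes.
#'
#' @param decomp a [svd_modes()] decomposition.
#' @param K integer vector of ensemble sizes (each <= `n_neurons`).
#' @param n_ensembles random ensembles per size.
#' @return an object of class `observation_fractions`: `eps` (M x
#'   length(K)), `K`, `offdiag` (largest off-diagonal magnitude of the
#'   averaged projector, per K — a diagnostic of the diagonal
#'   approximation), `n_ensembles`.
#' @export
observation_fractions <- function(decomp, K, n_ensembles = 200) {
  stopifnot(inherits(decomp, "mode_decomp"), all(K >= 1),
            all(K <= decomp$n_neurons))
  M <- decomp$M
  eps <- matrix(0, M, length(K))
  offd <- numeric(length(K))
  for (j in seq_along(K)) {
    Pbar <- matrix(0, M, M)
    if (K[j] == decomp$n_neurons) {
      Pbar <- .mode_projector(decomp, seq_len(decomp$n_neurons))
    } else {
      for (e in seq_len(n_ensembles)) {
        idx <- sample.int(decomp$n_neurons, K[j])
        Pbar <- Pbar + .mode_projector(decomp, idx)
      }
      Pbar <- Pbar / n_ensembles
    }
    eps[, j] <- diag(Pbar)
    od <- abs(Pbar - diag(diag(Pbar)))
    offd[j] <- if (length(od)) max(od) else 0
  }
  structure(list(eps = eps, K = as.integer(K), offdiag = offd,
                 n_ensembles = n_ensembles),
            class = "observation_fractions")
}

#' Analytic sensitivity and CC-indicator curves versus ensemble size
#'
#' The diagonal approximation of the ensemble-averaged sensitivity and
#' rescaled CC indicator: \eqn{\langle Y\rangle(K) \approx \sum_m
#' \epsilon_m(K) y_m} and \eqn{\langle Q\rangle(K) \approx [\sum_m
#' \epsilon_m(K) \lambda_m^2 y_m] / [N_{tot} \langle Y\rangle(K)]} (the
#' E[YQ] formula factorized as E[Y] E[Q]).
#'
#' @param decomp a [svd_modes()] decomposition.
#' @param fractions an [observation_fractions()] object.
#' @param tuning a [mode_tuning()] result.
#' @param n_total population size used in the 1/N normalization of Q
#'   (default `decomp$n_neurons`).
#' @return data.frame with columns `K`, `Y`, `Q`.
#' @export
approx_curves <- function(decomp, fractions, tuning,
                          n_total = decomp$n_neurons) {
  stopifnot(inherits(fractions, "observation_fractions"))
  Y <- as.numeric(crossprod(fractions$eps, tuning$y))
  YQ <- as.numeric(crossprod(fractions$eps, decomp$lambda^2 * tuning$y)) / n_total
  data.frame(K = fractions$K, Y = Y, Q = YQ / pmax(Y, .Machine$double.eps))
}

#' Exact mode-space quantities of one ensemble
#'
#' For a given ensemble (with negligible decision noise), the exact
#' sensitivity \eqn{Y = \sigma_s^2 \eta^\top P \eta}, total percept
#' covariance vector \eqn{e = \sigma_s^2 Y^{-1} U \Lambda P \eta} (the CC
#' prediction for every neuron, up to scaling), its regression coefficient
#' on tuning \eqn{Q = \langle e_i \bar b_i\rangle_i}, and the deviation
#' indicator V (computed from its definition with \eqn{\bar d =
#' \kappa\,(e - \sigma_s^2 \bar b)}). For the full population P = Id, e is
#' proportional to tuning and V = 0.
#'
#' @param decomp a [svd_modes()] decomposition.
#' @param tuning a [mode_tuning()] result.
#' @param ensemble integer indices of the ensemble's neurons.
#' @param kappa_val scaling factor \eqn{\kappa(Z)} entering `dbar` and `V`
#'   (default 1, i.e. V in units of kappa^2).
#' @param n_total population size for the 1/N averages (default
#'   `decomp$n_neurons`).
#' @return list with `Y`, `Z`, `e`, `Q`, `V`, `dbar`.
#' @export
exact_ensemble_quantities <- function(decomp, tuning, ensemble,
                                      kappa_val = 1,
                                      n_total = decomp$n_neurons) {
  stopifnot(inherits(decomp, "mode_decomp"))
  if (!length(ensemble)) stop("empty ensemble")
  P <- .mode_projector(decomp, ensemble)
  eta <- tuning$eta; s2 <- tuning$sigma_s2
  Y <- as.numeric(s2 * crossprod(eta, P %*% eta))
  if (Y <= 0) stop("ensemble carries no stimulus information (Y = 0)")
  e <- as.numeric(s2 / Y * (decomp$U %*% (decomp$lambda * (P %*% eta))))
  bbar <- as.numeric(decomp$U %*% (decomp$lambda * eta))
  Q <- sum(e * bbar) / n_total
  dbar <- kappa_val * (e - s2 * bbar)
  qbb <- sum(bbar * dbar) / n_total
  V <- (sum(bbar^2) / n_total) * (sum(dbar^2) / n_total) - qbb^2
  Z <- sqrt(max(s2 * (1 - Y) / Y, 0))
  list(Y = Y, Z = Z, e = e, Q = Q, V = V, dbar = dbar)
}

#' Rescalings between (Z, qbb) and (Y, Q)
#'
#' The sensitivity \eqn{Y = \sigma_s^2 / (Z^2 + \sigma_s^2)} maps the JND
#' onto [0, 1] (1 = perfect, 0 = no sensitivity); \eqn{Q = \kappa^{-1}
#' \bar{\bar q} + \sigma_s^2 \langle \bar b_i^2\rangle_i} is the matching
#' linear rescaling of the CC indicator. Both transforms and their inverses.
#'
#' @param Z JND (> 0); or `Y` in the inverse direction.
#' @param sigma_s2 stimulus variance (> 0).
#' @return `sensitivity_from_jnd` / `jnd_from_sensitivity` return scalars;
#'   `rescale_q` returns Q.
#' @export
sensitivity_from_jnd <- function(Z, sigma_s2) {
  stopifnot(all(Z >= 0), sigma_s2 > 0)
  sigma_s2 / (Z^2 + sigma_s2)
}

#' @rdname sensitivity_from_jnd
#' @param Y sensitivity in (0, 1].
#' @export
jnd_from_sensitivity <- function(Y, sigma_s2) {
  stopifnot(all(Y > 0), all(Y <= 1), sigma_s2 > 0)
  sqrt(sigma_s2 * (1 - Y) / Y)
}

#' @rdname sensitivity_from_jnd
#' @param qbb integrated tuning-CC indicator.
#' @param kappa_val scaling factor kappa(Z).
#' @param bbar2 population mean of squared integrated tuning.
#' @export
rescale_q <- function(qbb, kappa_val, sigma_s2, bbar2) {
  qbb / kappa_val + sigma_s2 * bbar2
}
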