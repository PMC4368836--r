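#' Parameter grid for the readout-scale inference
#'
#' Defaults reproduce the reference validation grid: K = 10:10:150 neurons,
#' w = 10:10:100 ms, t_R = 10:10:200 ms, sigma_d = 0:0.25:3 stimulus units,
#' with 2000 candidate ensembles per size K. `I` is the size of the
#' complementary set used to predict out-of-ensemble choice covariances;
#' when NULL it defaults to `min pool size - max(K)`.
#'
#' @param K ensemble sizes (neurons).
#' @param w integration windows (seconds).
#' @param t_R extraction times (seconds).
#' @param sigma_d decision-noise values (stimulus units).
#' @param n_ensembles total candidate ensembles per K (spread over pools).
#' @param I complementary-set size, or NULL for the default.
#' @return an object of class `readout_grid`.
#' @export
readout_grid <- function(K = seq(10, 150, 10), w = seq(0.01, 0.1, 0.01),
                         t_R = seq(0.01, 0.2, 0.01),
                         sigma_d = seq(0, 3, 0.25),
                         n_ensembles = 2000, I = NULL) {
  stopifnot(all(K >= 1), all(w > 0), all(t_R > 0), all(sigma_d >= 0),
            n_ensembles >= 1)
  structure(list(K = sort(unique(as.integer(K))), w = sort(unique(w)),
                 t_R = sort(unique(t_R)), sigma_d = sort(unique(sigma_d)),
                 n_ensembles = as.integer(n_ensembles), I = I),
            class = "readout_grid")
}

#' Sample candidate readout ensembles
#'
#' Draws `n_ensembles` candidate ensembles of size K, each uniformly
#' without replacement within a single recording pool (cycling over
#' pools), together with a disjoint complementary set of I neurons from
#' the same pool.
#'
#' @param data a [spike_dataset()].
#' @param K ensemble size.
#' @param n_ensembles number of ensembles.
#' @param I complementary-set size.
#' @param seed RNG seed.
#' @return list of records `list(pool, ensemble, iset)` (neuron ids).
#' @export
sample_ensembles <- function(data, K, n_ensembles, I, seed = 1) {
  stopifnot(inherits(data, "spike_dataset"))
  sizes <- lengths(data$pools)
  if (any(K + I > sizes))
    stop(sprintf("K + I = %d exceeds the smallest pool size (%d)",
                 K + I, min(sizes)))
  set.seed(stream_seed(seed, "ensembles"))
  pool_seq <- rep_len(names(data$pools), n_ensembles)
  lapply(seq_len(n_ensembles), function(e) {
    p <- pool_seq[e]
    pick <- sample(data$pools[[p]], K + I)
    list(pool = p, ensemble = sort(pick[seq_len(K)]),
         iset = sort(pick[K + seq_len(I)]))
  })
}

#' Empirical-Bayes ridge strength for the regularized discriminant
#'
#' With few trials the Fisher discriminant overfits the noise covariance
#' and overestimates sensitivity. The ridge strength is chosen by evidence
#' maximization for the Bayesian linear regression of the stimulus on the
#' integrated counts (spherical Gaussian prior on the weights): the
#' Gaussian marginal likelihood, built from the moment inputs, is scanned
#' over a log-spaced lambda grid. Deterministic given its inputs; lambda
#' shrinks to 0 as trials accumulate on a well-conditioned covariance and
#' is strictly positive when the covariance is rank deficient.
#'
#' @param Cbb restricted noise covariance matrix (K x K).
#' @param bbar restricted integrated tuning (length K).
#' @param n_trials number of trials behind the estimates (> 1).
#' @param sigma_s2 stimulus variance across trials.
#' @param lambda_grid candidate ridge values; default log-spaced relative
#'   to the mean diagonal of `Cbb`.
#' @return the selected lambda (same units as the covariance diagonal).
#' @export
choose_regularization <- function(Cbb, bbar, n_trials, sigma_s2 = 1,
                                  lambda_grid = NULL) {
  stopifnot(n_trials > 1, length(bbar) == nrow(Cbb))
  Cbb <- (Cbb + t(Cbb)) / 2
  A <- Cbb + sigma_s2 * tcrossprod(bbar)
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("covariance input is not positive semi-definite")
  d <- pmax(e$values, 0)
  z <- as.numeric(crossprod(e$vectors, bbar))
  if (is.null(lambda_grid)) {
    scale <- mean(diag(Cbb))
    if (scale <= 0) scale <- 1
    lambda_grid <- scale * 10^seq(-8, 3, length.out = 56)
  }
  n <- n_trials
  ev <- vapply(lambda_grid, function(lam) {
    rss <- n * sigma_s2 - n * sigma_s2^2 * sum(z^2 / (d + lam))
    rss <- max(rss, 1e-12 * n * sigma_s2)
    -0.5 * sum(log((d + lam) / lam)) - n / 2 * log(rss / n)
  }, numeric(1))
  lambda_grid[which.max(ev)]
}

#' Bi-temporal Gaussian smoothing of q(u, t)
#'
#' Separable Gaussian convolution along both time axes with reflecting
#' boundaries; mitigates the measurement noise of the tuning-CC indicator
#' before it enters the statistical loss. A constant field is left
#' unchanged and total mass is preserved away from the edges.
#'
#' @param q bin x bin matrix on a regular grid.
#' @param delta bin width, seconds.
#' @param sd Gaussian time constant, seconds (default 10 ms).
#' @return the smoothed matrix.
#' @export
smooth_q <- function(q, delta, sd = 0.01) {
  q <- as.matrix(q)
  Sm <- .gauss_smoother(nrow(q), delta, sd)
  Sm2 <- if (ncol(q) == nrow(q)) Sm else .gauss_smoother(ncol(q), delta, sd)
  Sm %*% q %*% t(Sm2)
}

.gauss_smoother <- function(B, delta, sd) {
  if (sd <= 0) return(diag(B))
  r <- max(1L, ceiling(4 * sd / delta))
  g <- dnorm((-r:r) * delta, 0, sd)
  g <- g / sum(g)
  Sm <- matrix(0, B, B)
  for (i in seq_len(B)) {
    idx <- i + (-r:r)
    idx <- ifelse(idx < 1L, 1L - idx, idx)          # reflect at the left edge
    idx <- ifelse(idx > B, 2L * B + 1L - idx, idx)  # and at the right edge
    idx <- pmin(pmax(idx, 1L), B)
    for (k in seq_along(idx)) Sm[i, idx[k]] <- Sm[i, idx[k]] + g[k]
  }
  Sm
}

#' Measurement-noise correction of the indicator V
#'
#' V is built from squared quantities, so measurement noise in the
#' integrated tuning and CC inflates it systematically (like the naive
#' variance estimator before the n/(n-1) correction). Bootstrap resamples
#' provide per-neuron sampling variances of `bbar` and `dbar` and their
#' sampling covariance; these are subtracted from the second moments and
#' from the cross term before V is formed. The corrected value can be
#' negative when the true V is at the noise floor; it is reported as-is
#' with a flag.
#'
#' @param bbar,dbar measured integrated tuning and CC per neuron.
#' @param boot_bbar,boot_dbar matrices (neuron x resamples) of the same
#'   quantities on bootstrap resamples; NULL falls back to the raw V with
#'   a warning.
#' @return list with `V` (corrected), `V_raw`, `qbb` (corrected cross
#'   term), `at_noise_floor` flag.
#' @export
debias_V <- function(bbar, dbar, boot_bbar = NULL, boot_dbar = NULL) {
  V_raw <- indicator_V(bbar, dbar)
  if (is.null(boot_bbar) || is.null(boot_dbar) ||
      NCOL(boot_bbar) < 2 || NCOL(boot_dbar) < 2) {
    warning("no bootstrap resamples available; returning the uncorrected V")
    return(list(V = V_raw, V_raw = V_raw, qbb = mean(bbar * dbar),
                at_noise_floor = FALSE))
  }
  vb <- apply(boot_bbar, 1, var)
  vd <- apply(boot_dbar, 1, var)
  cbd <- vapply(seq_len(nrow(boot_bbar)), function(i)
    cov(boot_bbar[i, ], boot_dbar[i, ]), numeric(1))
  b2 <- mean(bbar^2) - mean(vb)
  d2 <- mean(dbar^2) - mean(vd)
  qbb <- mean(bbar * dbar) - mean(cbd)
  V <- b2 * d2 - qbb^2
  list(V = V, V_raw = V_raw, qbb = qbb, at_noise_floor = V <= 0)
}

#' Case-1 loss: direct readout fit with full population coverage
#'
#' When every neuron is recorded simultaneously, the characteristic
#' equations constrain the readout weights directly and the readout
#' parameters minimize
#' \deqn{L = (1 - \bar b^\top a)^2 + \lambda_w (Z^{*2} - \sigma_d^2 -
#' a^\top \bar{\bar C} a)^2 + \mu_w \int dt\, \| d^*(t) - \kappa(Z^*) \bar
#' C(t) a \|^2.}
#'
#' @param istats an `integrated_stats` object for the full population
#'   (`Cbar` and `Cbb` complete).
#' @param d_star measured CC curves, neuron x bin.
#' @param Z_star measured JND.
#' @param a candidate readout weights.
#' @param sigma_d candidate decision noise.
#' @param lambda_w,mu_w loss weights for the variance and CC terms.
#' @param kappa_star scaling factor kappa evaluated at the measured JND.
#' @return the loss value.
#' @export
loss_case1 <- function(istats, d_star, Z_star, a, sigma_d,
                       lambda_w = 1, mu_w = 1, kappa_star = 1) {
  stopifnot(inherits(istats, "integrated_stats"))
  if (is.null(istats$Cbar)) stop("complete covariance curves required")
  pm <- predict_moments(a, istats)
  cc_err <- d_star - kappa_star * pm$cov_t
  (1 - pm$slope)^2 +
    lambda_w * (Z_star^2 - sigma_d^2 - pm$variance)^2 +
    mu_w * sum(cc_err^2) * istats$delta
}

## ---------------------------------------------------------------------
## shared preparation for the Case-2 grid search
## ---------------------------------------------------------------------

## per-pool binned arrays plus measured time-resolved statistics
.inference_prep <- function(data, delta) {
  pools <- names(data$pools)
  stimuli <- stimulus_set(data)
  prep <- list(pools = list(), stimuli = stimuli$s, n_s = stimuli$n,
               s0 = data$s0, n_total = data$n_total, delta = delta)
  for (p in pools) {
    bp <- .bin_pool(data, p, delta)
    n <- nrow(bp$trials); N <- length(bp$neurons); B <- dim(bp$R)[3]
    s <- bp$trials$s; ch <- bp$trials$choice
    ## measured tuning and CC on the bin grid (pool-local)
    st <- sort(unique(s))
    ns <- vapply(st, function(v) sum(s == v), numeric(1))
    Rm <- matrix(bp$R, nrow = n)                        # n x (N*B)
    gm <- t(vapply(st, function(v) colMeans(Rm[s == v, , drop = FALSE]),
                   numeric(N * B)))
    sbar <- sum(ns * st) / sum(ns)
    bvec <- colSums(ns * (st - sbar) * gm) / sum(ns * (st - sbar)^2)
    bmat <- matrix(bvec, N, B)
    dmat <- matrix(0, N, B)
    if (!all(is.na(ch))) {
      for (j in seq_along(st)) {
        sel <- s == st[j]
        cc <- ch[sel]
        dv <- colMeans(Rm[sel, , drop = FALSE] * cc) -
          colMeans(Rm[sel, , drop = FALSE]) * mean(cc)
        dmat <- dmat + matrix(dv, N, B) * (ns[j] / n)
      }
    }
    Rc <- .center_by_stim(bp$R, s)
    denom <- attr(Rc, "denom")
    prep$pools[[p]] <- list(
      n = n, N = N, B = B, s = s, choice = ch, neurons = bp$neurons,
      Rm_raw = matrix(bp$R, nrow = n * N),              # (n*N) x B
      Rc = Rc,
      denom = denom, bmat = bmat, dmat = dmat,
      st = st, ns = ns)
    prep$breaks <- bp$breaks; prep$mids <- bp$mids
  }
  prep$B <- length(prep$mids)
  prep$sigma_s2 <- local({
    s <- data$trials$s
    mean(s^2) - mean(s)^2
  })
  prep
}

## analytic sampling variances of the integrated tuning and CC of one pool:
## Var(bbar_i) = Cbb_ii / (n sigma_s^2) (weighted regression slope),
## Var(dbar_i) = Cbb_ii * sum_s n_s psi_s(1-psi_s) / n^2 + dbar_i^2 / n
## (variance of the trial-weighted within-stimulus covariance with choice)
.pool_meas_var <- function(pp, Cbb_diag, bbar, dbar, sigma_s2) {
  n <- pp$n
  psis <- vapply(pp$st, function(v) mean(pp$choice[pp$s == v]), numeric(1))
  ccoef <- sum(pp$ns * psis * (1 - psis)) / n^2
  list(vb = Cbb_diag / (n * sigma_s2),
       vd = Cbb_diag * ccoef + dbar^2 / n)
}

## integrated tuning / CC of one pool for one kernel weight vector;
## optionally on a row subset (bootstrap resample)
.pool_integrated <- function(pp, kw, rows = NULL, rbar = NULL) {
  if (is.null(rbar)) rbar <- matrix(pp$Rm_raw %*% kw, pp$n, pp$N)
  if (!is.null(rows)) {
    rbar <- rbar[rows, , drop = FALSE]
    s <- pp$s[rows]; ch <- pp$choice[rows]
  } else {
    s <- pp$s; ch <- pp$choice
  }
  st <- sort(unique(s))
  ns <- vapply(st, function(v) sum(s == v), numeric(1))
  gm <- t(matrix(vapply(st, function(v)
    colMeans(rbar[s == v, , drop = FALSE]), numeric(pp$N)), nrow = pp$N))
  sbar <- sum(ns * st) / sum(ns)
  bbar <- colSums(ns * (st - sbar) * gm) / sum(ns * (st - sbar)^2)
  dbar <- numeric(pp$N)
  if (!all(is.na(ch))) {
    for (j in seq_along(st)) {
      sel <- s == st[j]
      cc <- ch[sel]
      dbar <- dbar + (ns[j] / length(s)) *
        (colMeans(rbar[sel, , drop = FALSE] * cc) -
           colMeans(rbar[sel, , drop = FALSE]) * mean(cc))
    }
  }
  list(bbar = as.numeric(bbar), dbar = dbar, rbar = rbar)
}

#' Model predictions of the population indicators for one grid cell
#'
#' For a candidate parameter set (K, w, t_R, sigma_d): samples random
#' ensembles within the recording pools, computes each one's regularized
#' optimal readout and the resulting predicted JND, CC curves
#' (within-ensemble and on the disjoint complementary set), mixes the two
#' with weight p = K / N_tot, and averages across ensembles.
#'
#' @param data a [spike_dataset()] with choices.
#' @param K,w,t_R,sigma_d candidate readout parameters.
#' @param n_ensembles candidate ensembles.
#' @param I complementary-set size (default: smallest pool minus K).
#' @param delta bin width, seconds.
#' @param lambda ridge: `"auto"` or a number.
#' @param Z_star measured JND used inside kappa (fitted from the data
#'   when NULL).
#' @param debias logical: subtract the analytic sampling-noise terms from
#'   the squared-indicator predictions (see [fit_readout_scales()])?
#' @param seed RNG seed for the ensemble sampling.
#' @return list with `Z2` (mean predicted Z^2), `q` (bin x bin predicted
#'   indicator), `V` (mean predicted deviation), `S` (per-ensemble percept
#'   noise variances).
#' @export
predict_indicators <- function(data, K, w, t_R, sigma_d = 0,
                               n_ensembles = 200, I = NULL, delta = 0.01,
                               lambda = "auto", Z_star = NULL, debias = TRUE,
                               seed = 1) {
  prep <- .inference_prep(data, delta)
  if (is.null(I)) I <- max(min(lengths(data$pools)) - K, 10L)
  if (is.null(Z_star)) {
    psy <- fit_psychometric(data)
    Z_star <- psy$Z; mu_d <- psy$mu_d
  } else mu_d <- 0
  kap <- kappa(Z_star, prep$stimuli, prep$n_s, mu_d, prep$s0)
  kernel <- temporal_kernel("square", w = w, t_R = t_R)
  ens <- .ensembles_by_pool(data, K, n_ensembles, I, seed)
  cell <- .scan_kernel(prep, kernel, list(K), list(ens), lambda)
  agg <- .aggregate_cell(cell[[1]], K, I, prep$n_total, kap, n_ensembles,
                         debias = debias)
  list(Z2 = mean(agg$S[is.finite(agg$S)]) + sigma_d^2,
       q = agg$q, V = agg$V, S = agg$S)
}

## ensembles as per-pool index matrices: list over pools of list(E, I)
.ensembles_by_pool <- function(data, K, n_ensembles, I, seed) {
  recs <- sample_ensembles(data, K, n_ensembles, I, seed)
  out <- list()
  for (p in names(data$pools)) {
    sel <- recs[vapply(recs, function(r) r$pool == p, logical(1))]
    if (!length(sel)) next
    out[[p]] <- list(
      E = vapply(sel, function(r) match(r$ensemble, data$pools[[p]]),
                 integer(K)),
      I = vapply(sel, function(r) match(r$iset, data$pools[[p]]),
                 integer(I)))
    if (K == 1L) out[[p]]$E <- matrix(out[[p]]$E, nrow = 1L)
    if (I == 1L) out[[p]]$I <- matrix(out[[p]]$I, nrow = 1L)
  }
  out
}

## run the compiled scan for one kernel over all pools and K values.
## K_list: list of K; ens_list: parallel list of per-pool ensemble sets.
## Returns per-K list of per-pool raw results plus pool moments.
.scan_kernel <- function(prep, kernel, K_list, ens_list, lambda) {
  kw <- kernel_weights(kernel, prep$breaks)
  pools <- names(prep$pools)
  moments <- list()
  for (p in pools) {
    pp <- prep$pools[[p]]
    rbar <- matrix(pp$Rm_raw %*% kw, pp$n, pp$N)
    rbarc <- .center_by_stim(rbar, pp$s)
    Cbb <- crossprod(rbarc) / pp$denom
    Cbb <- (Cbb + t(Cbb)) / 2
    pi <- .pool_integrated(pp, kw, rbar = rbar)
    moments[[p]] <- list(rbarc = rbarc, Cbb = Cbb, bbar = pi$bbar,
                         dbar = pi$dbar)
  }
  sigma_s2 <- local({
    s <- unlist(lapply(prep$pools, `[[`, "s"), use.names = FALSE)
    mean(s^2) - mean(s)^2
  })
  out <- vector("list", length(K_list))
  for (ki in seq_along(K_list)) {
    K <- K_list[[ki]]
    per_pool <- list()
    for (p in pools) {
      es <- ens_list[[ki]][[p]]
      if (is.null(es)) next
      mo <- moments[[p]]
      lam <- if (identical(lambda, "auto")) {
        e1 <- es$E[, 1]
        choose_regularization(mo$Cbb[e1, e1, drop = FALSE], mo$bbar[e1],
                              n_trials = prep$pools[[p]]$n,
                              sigma_s2 = sigma_s2)
      } else lambda
      res <- ensemble_scan_cpp(prep$pools[[p]]$Rc, mo$rbarc, mo$Cbb,
                               mo$bbar, prep$pools[[p]]$bmat,
                               list(es$E), list(es$I), lam,
                               prep$pools[[p]]$denom)[[1]]
      res$nE <- ncol(es$E)
      res$lambda <- lam
      res$denom <- prep$pools[[p]]$denom
      res$sigma_s2 <- sigma_s2
      per_pool[[p]] <- res
    }
    out[[ki]] <- per_pool
  }
  attr(out, "moments") <- moments
  out
}

## combine the per-pool raw scan outputs of one (kernel, K) cell.
## The squared-indicator predictions <bbar^2>, <dbar^2> are themselves
## estimates built from finitely many trials; their sampling noise inflates
## the predicted V just as measurement noise inflates the measured V.
## With debias = TRUE the analytic noise variances are subtracted:
##   Var(bbar_i)  ~ Cbb_ii / (n sigma_s^2)
##   Var(dbar_i)  ~ kappa^2 (Cbb_ii * S_e + dbar_i^2) / n
## (the variance of a sample covariance between the binned counts and the
## percept projection of noise variance S_e).
.aggregate_cell <- function(per_pool, K, I, n_total, kap, n_ensembles,
                            debias = TRUE) {
  S <- unlist(lapply(per_pool, `[[`, "S"), use.names = FALSE)
  nEs <- vapply(per_pool, `[[`, numeric(1), "nE")
  Qin <- Reduce(`+`, Map(function(r) r$nE * r$Qin, per_pool)) / sum(nEs)
  Qout <- Reduce(`+`, Map(function(r) r$nE * r$Qout, per_pool)) / sum(nEs)
  q <- kap * mix_in_out(Qin, Qout, K, n_total)
  st <- do.call(cbind, lapply(per_pool, `[[`, "st6"))
  Se <- S
  dn <- unlist(lapply(per_pool, function(r) rep(r$denom, r$nE)),
               use.names = FALSE)
  s2 <- per_pool[[1]]$sigma_s2
  bb_in <- st[1, ]; bb_out <- st[2, ]
  db_in <- st[5, ]; db_out <- st[6, ]
  qbb_in <- st[3, ]; qbb_out <- st[4, ]
  if (debias) {
    vb_in <- st[7, ] / (dn * s2)        # Var(bbar_i) within the ensemble
    bb_in <- bb_in - vb_in
    bb_out <- bb_out - st[8, ] / (dn * s2)
    ## in-part CC prediction is S_e * bbar_i: noise S_e^2 Var(bbar_i)
    db_in <- db_in - Se^2 * vb_in
    qbb_in <- qbb_in - Se * vb_in
    db_out <- db_out - (st[8, ] * Se + db_out) / dn
  }
  bb2 <- mix_in_out(bb_in, bb_out, K, n_total)
  qbb <- kap * mix_in_out(qbb_in, qbb_out, K, n_total)
  db2 <- kap^2 * mix_in_out(db_in, db_out, K, n_total)
  V_e <- bb2 * db2 - qbb^2
  if (debias) {
    ## finite-neuron sampling corrections: the set averages behind qbb^2
    ## and <b^2><d^2> are noisy, which biases the squared/cross terms
    p <- K / n_total
    var_qbb <- kap^2 * (p^2 * st[9, ] + (1 - p)^2 * st[10, ])
    cov_b2d2 <- kap^2 * (p^2 * st[11, ] + (1 - p)^2 * st[12, ])
    V_e <- V_e + var_qbb - cov_b2d2
  }
  list(S = S, q = q, V = mean(V_e[is.finite(V_e)]), V_e = V_e)
}

#' Recover the readout scales by the statistical grid search
#'
#' The Case-2 inference: measured indicators (psychometric JND Z*, the
#' smoothed tuning-CC field q*(u, t), and the noise-corrected deviation
#' V*) are compared against their model predictions over a 4-d grid of
#' candidate parameters (K, w, t_R, sigma_d), using the statistical loss
#' \deqn{L = (Z^{*2} - \langle Z^2\rangle)^2 + \lambda \int\!\!\int (q^* -
#' \langle q\rangle)^2 + \mu (V^* - \langle V\rangle)^2,}
#' with weights set by the power of the measured indicators
#' (\eqn{\lambda = Z^{*4}/\int\!\!\int q^{*2}}, \eqn{\mu = Z^{*4}/V^{*2}}).
#' Predictions average over random candidate ensembles within the
#' recording pools; the restricted discriminants are ridge-regularized
#' (empirical Bayes) and q fields are smoothed with a 10 ms bi-temporal
#' Gaussian. Ties are broken towards parsimony (smallest K, then w, t_R,
#' sigma_d).
#'
#' @param data a [spike_dataset()] with choices and pools.
#' @param grid a [readout_grid()].
#' @param delta bin width, seconds.
#' @param smooth_sd Gaussian smoothing time constant for q, seconds.
#' @param lambda ridge: `"auto"` (per pool/kernel/K, empirical Bayes on a
#'   representative ensemble) or a number.
#' @param n_vboot bootstrap resamples behind the V* correction when
#'   `debias = "bootstrap"`.
#' @param debias noise correction of the V indicator: `"analytic"`
#'   (default; closed-form sampling-variance subtraction on both the
#'   measured and the predicted side), `"bootstrap"` (trial-resampling
#'   estimate, see [debias_V()]), or `"none"`.
#' @param seed master seed (ensemble sampling and bootstrap streams).
#' @param verbose print progress?
#' @return an object of class `readout_fit`; see [print.readout_fit()].
#'   Elements include `best` (the fitted parameters), `loss` (the full 4-d
#'   array), the per-cell predicted indicators, and the measured
#'   indicators.
#' @export
fit_readout_scales <- function(data, grid = readout_grid(), delta = 0.01,
                               smooth_sd = 0.01, lambda = "auto",
                               n_vboot = 14,
                               debias = c("analytic", "bootstrap", "none"),
                               seed = 1, verbose = FALSE) {
  stopifnot(inherits(data, "spike_dataset"), inherits(grid, "readout_grid"))
  debias <- match.arg(debias)
  if (all(is.na(data$trials$choice)))
    stop("dataset has no choices; generate behavior first")
  t0 <- proc.time()[3]
  sizes <- lengths(data$pools)
  I <- grid$I
  if (is.null(I)) I <- min(sizes) - max(grid$K)
  if (I < 1) stop("complementary set empty: max(K) too close to pool size")
  if (max(grid$K) + I > min(sizes))
    stop("K + I exceeds the smallest pool size")
  prep <- .inference_prep(data, delta)
  ## measured indicators ------------------------------------------------
  psy <- fit_psychometric(data)
  Z_star <- psy$Z
  kap <- kappa(Z_star, prep$stimuli, prep$n_s, psy$mu_d, prep$s0)
  bmat_all <- do.call(rbind, lapply(prep$pools, `[[`, "bmat"))
  dmat_all <- do.call(rbind, lapply(prep$pools, `[[`, "dmat"))
  q_star <- indicator_q(bmat_all, dmat_all)$q
  q_star_s <- smooth_q(q_star, delta, smooth_sd)
  qq_power <- sum(q_star_s^2) * delta^2
  ## bootstrap resample indices (per pool, reused across kernels)
  boot_rows <- NULL
  if (debias == "bootstrap") {
    set.seed(stream_seed(seed, "vboot"))
    boot_rows <- lapply(prep$pools, function(pp)
      lapply(seq_len(n_vboot), function(b)
        unlist(lapply(split(seq_len(pp$n), pp$s), function(idx)
          idx[sample.int(length(idx), length(idx), replace = TRUE)]),
          use.names = FALSE)))
  }
  ## candidate ensembles (per K, reused across kernels)
  ens_all <- lapply(seq_along(grid$K), function(ki)
    .ensembles_by_pool(data, grid$K[ki], grid$n_ensembles, I,
                       seed = stream_seed(seed, paste0("ens-K", grid$K[ki]))))
  ## kernel sweep --------------------------------------------------------
  nw <- length(grid$w); nt <- length(grid$t_R); nK <- length(grid$K)
  nsd <- length(grid$sigma_d)
  S_bar <- array(NA_real_, c(nw, nt, nK))
  V_bar <- array(NA_real_, c(nw, nt, nK))
  q_term <- array(NA_real_, c(nw, nt, nK))
  V_star <- matrix(NA_real_, nw, nt)
  for (iw in seq_len(nw)) for (it in seq_len(nt)) {
    kernel <- temporal_kernel("square", w = grid$w[iw], t_R = grid$t_R[it])
    kw <- kernel_weights(kernel, prep$breaks)
    ## measured integrated indicators for this kernel
    rbars <- lapply(prep$pools, function(pp)
      matrix(pp$Rm_raw %*% kw, pp$n, pp$N))
    meas <- Map(function(pp, rb) .pool_integrated(pp, kw, rbar = rb),
                prep$pools, rbars)
    bbar_all <- unlist(lapply(meas, `[[`, "bbar"), use.names = FALSE)
    dbar_all <- unlist(lapply(meas, `[[`, "dbar"), use.names = FALSE)
    if (debias == "bootstrap" && n_vboot >= 2) {
      bb <- db <- NULL
      for (b in seq_len(n_vboot)) {
        mb <- Map(function(pp, rows, rb)
          .pool_integrated(pp, kw, rows[[b]], rbar = rb),
          prep$pools, boot_rows, rbars)
        bb <- cbind(bb, unlist(lapply(mb, `[[`, "bbar"), use.names = FALSE))
        db <- cbind(db, unlist(lapply(mb, `[[`, "dbar"), use.names = FALSE))
      }
      V_star[iw, it] <- debias_V(bbar_all, dbar_all, bb, db)$V
    } else if (debias == "analytic") {
      mv <- Map(function(pp, rb, me) {
        rc <- .center_by_stim(rb, pp$s)
        .pool_meas_var(pp, colSums(rc^2) / attr(rc, "denom"),
                       me$bbar, me$dbar, prep$sigma_s2)
      }, prep$pools, rbars, meas)
      vb <- unlist(lapply(mv, `[[`, "vb"), use.names = FALSE)
      vd <- unlist(lapply(mv, `[[`, "vd"), use.names = FALSE)
      nn <- length(bbar_all)
      V_star[iw, it] <- (mean(bbar_all^2) - mean(vb)) *
        (mean(dbar_all^2) - mean(vd)) - mean(bbar_all * dbar_all)^2 +
        var(bbar_all * dbar_all) / nn -
        cov(bbar_all^2, dbar_all^2) / nn
    } else {
      V_star[iw, it] <- indicator_V(bbar_all, dbar_all)
    }
    cells <- .scan_kernel(prep, kernel, as.list(grid$K), ens_all, lambda)
    for (ki in seq_len(nK)) {
      agg <- .aggregate_cell(cells[[ki]], grid$K[ki], I, prep$n_total,
                             kap, grid$n_ensembles,
                             debias = debias != "none")
      S_bar[iw, it, ki] <- mean(agg$S[is.finite(agg$S)])
      V_bar[iw, it, ki] <- agg$V
      qp <- smooth_q(agg$q, delta, smooth_sd)
      q_term[iw, it, ki] <- sum((q_star_s - qp)^2) * delta^2
    }
    if (verbose)
      message(sprintf("kernel w = %3.0f ms, t_R = %3.0f ms done (%.0f s)",
                      1e3 * grid$w[iw], 1e3 * grid$t_R[it],
                      proc.time()[3] - t0))
  }
  ## loss assembly -------------------------------------------------------
  ## single scalar weights set by the power of the measured indicators;
  ## for V the mean squared field across kernels (the analogue of the
  ## integrated q* power), so that cells where the noisy V* happens to be
  ## near zero are not infinitely amplified
  lambda_w <- Z_star^4 / qq_power
  mu_w <- Z_star^4 / max(mean(V_star^2), .Machine$double.xmin)
  loss <- array(NA_real_, c(nw, nt, nK, nsd),
                dimnames = list(w = 1e3 * grid$w, t_R = 1e3 * grid$t_R,
                                K = grid$K, sigma_d = grid$sigma_d))
  for (isd in seq_len(nsd)) {
    Z2_pred <- S_bar + grid$sigma_d[isd]^2
    loss[, , , isd] <- (Z_star^2 - Z2_pred)^2 + lambda_w * q_term +
      mu_w * (array(V_star, c(nw, nt, nK)) - V_bar)^2
  }
  cells <- expand.grid(iw = seq_len(nw), it = seq_len(nt),
                       ik = seq_len(nK), isd = seq_len(nsd))
  cells$loss <- as.numeric(loss)
  ord <- order(cells$loss, grid$K[cells$ik], grid$w[cells$iw],
               grid$t_R[cells$it], grid$sigma_d[cells$isd])
  top <- cells[ord[1], ]
  best <- c(w = grid$w[top$iw], t_R = grid$t_R[top$it], K = grid$K[top$ik],
            sigma_d = grid$sigma_d[top$isd])
  structure(list(
    best = best, loss_min = top$loss, loss = loss,
    S_bar = S_bar, V_bar = V_bar, q_term = q_term,
    measured = list(Z_star = Z_star, mu_d = psy$mu_d, kappa = kap,
                    q_star = q_star_s, V_star = V_star,
                    psychometry = psy),
    weights = list(lambda = lambda_w, mu = mu_w),
    grid = grid, I = I, delta = delta, smooth_sd = smooth_sd,
    n_total = prep$n_total, seed = seed,
    elapsed = proc.time()[3] - t0, call = match.call()),
    class = "readout_fit")
}

#' @export
print.readout_fit <- function(x, ...) {
  cat("Readout-scale inference (statistical grid search)\n")
  cat(sprintf("  measured JND Z* = %.3g (mu_d = %.3g)\n",
              x$measured$Z_star, x$measured$mu_d))
  cat(sprintf("  best fit: w = %g ms, t_R = %g ms, K = %d, sigma_d = %g\n",
              1e3 * x$best[["w"]], 1e3 * x$best[["t_R"]],
              as.integer(x$best[["K"]]), x$best[["sigma_d"]]))
  cat(sprintf("  loss %.4g over a %d-cell grid (%.1f s)\n",
              x$loss_min, length(x$loss), x$elapsed))
  invisible(x)
}

#' @export
coef.readout_fit <- function(object, ...) object$best

#' @export
summary.readout_fit <- function(object, ...) {
  g <- object$grid
  bi <- c(which(g$w == object$best[["w"]]),
          which(g$t_R == object$best[["t_R"]]),
          which(g$K == object$best[["K"]]))
  out <- list(
    best = object$best,
    Z_star = object$measured$Z_star,
    Z_pred = sqrt(object$S_bar[bi[1], bi[2], bi[3]] +
                    object$best[["sigma_d"]]^2),
    V_star = object$measured$V_star[bi[1], bi[2]],
    V_pred = object$V_bar[bi[1], bi[2], bi[3]],
    q_term = object$q_term[bi[1], bi[2], bi[3]],
    weights = object$weights[c("lambda")],
    elapsed = object$elapsed)
  class(out) <- "summary.readout_fit"
  out
}

#' @export
print.summary.readout_fit <- function(x, ...) {
  cat(sprintf("best fit: w = %g ms, t_R = %g ms, K = %d, sigma_d = %g\n",
              1e3 * x$best[["w"]], 1e3 * x$best[["t_R"]],
              as.integer(x$best[["K"]]), x$best[["sigma_d"]]))
  cat(sprintf("  JND: measured %.3g, predicted %.3g\n", x$Z_star, x$Z_pred))
  cat(sprintf("  V:   measured %.3g, predicted %.3g\n", x$V_star, x$V_pred))
  cat(sprintf("  q mean-square mismatch: %.4g\n", x$q_term))
  invisible(x)
}

#' Loss-surface projections of a readout fit
#'
#' Two panels: the q-driven loss over the (w, t_R) plane (at the best K and
#' sigma_d) and the full loss over the (K, w) plane (at the best t_R and
#' sigma_d), with the best fit marked.
#'
#' @param x a `readout_fit`.
#' @param ... passed to [graphics::image()].
#' @export
plot.readout_fit <- function(x, ...) {
  g <- x$grid
  bi <- list(w = which(g$w == x$best[["w"]]),
             t = which(g$t_R == x$best[["t_R"]]),
             k = which(g$K == x$best[["K"]]),
             s = which(g$sigma_d == x$best[["sigma_d"]]))
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  image(1e3 * g$t_R, 1e3 * g$w, t(x$q_term[, , bi$k]),
        xlab = "t_R (ms)", ylab = "w (ms)",
        main = "q-term", col = hcl.colors(64, "viridis"), ...)
  points(1e3 * x$best[["t_R"]], 1e3 * x$best[["w"]], pch = 0, cex = 2,
         col = "white", lwd = 2)
  image(g$K, 1e3 * g$w, t(x$loss[, bi$t, , bi$s]),
        xlab = "K (neurons)", ylab = "w (ms)",
        main = "loss (best t_R, sigma_d)", col = hcl.colors(64, "viridis"),
        ...)
  points(x$best[["K"]], 1e3 * x$best[["w"]], pch = 0, cex = 2,
         col = "white", lwd = 2)
  invisible(x)
}

#' Bootstrap confidence regions for the readout scales
#'
#' Repeats the full grid-search fit on trial-level bootstrap resamples
#' (with replacement, stratified by pool and stimulus) and summarizes the
#' scatter of the resampled best fits as 1- and 2-standard-deviation
#' ellipses in each 2-d projection of the parameter space.
#'
#' @param data a [spike_dataset()] with choices.
#' @param grid a [readout_grid()].
#' @param n_boot bootstrap resamples (>= 2; default 14).
#' @param seed master seed.
#' @param ... further arguments passed to [fit_readout_scales()].
#' @return an object of class `readout_boot`: `fits` (n_boot x 4 matrix of
#'   best fits), `center`, `cov`, `ellipses` (per projection, polygons at
#'   1 and 2 SD).
#' @export
bootstrap_fit <- function(data, grid = readout_grid(), n_boot = 14,
                          seed = 1, ...) {
  stopifnot(n_boot >= 2)
  fits <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("w", "t_R", "K", "sigma_d")))
  for (b in seq_len(n_boot)) {
    set.seed(stream_seed(seed, paste0("boot-", b)))
    db <- resample_trials(data)
    fb <- fit_readout_scales(db, grid,
                             seed = stream_seed(seed, paste0("bootfit-", b)),
                             ...)
    fits[b, ] <- fb$best
  }
  center <- colMeans(fits)
  S <- cov(fits)
  pairs <- list(c("t_R", "w"), c("K", "w"), c("K", "sigma_d"))
  ellipses <- lapply(pairs, function(pr) {
    mu <- center[pr]; Sg <- S[pr, pr]
    list(pair = pr,
         sd1 = .ellipse_points(mu, Sg, 1),
         sd2 = .ellipse_points(mu, Sg, 2))
  })
  structure(list(fits = fits, center = center, cov = S,
                 ellipses = ellipses, n_boot = n_boot, seed = seed),
            class = "readout_boot")
}

.ellipse_points <- function(mu, Sigma, r, n = 100) {
  th <- seq(0, 2 * pi, length.out = n)
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(mu))
  pts <- t(mu + r * (L %*% rbind(cos(th), sin(th))))
  colnames(pts) <- names(mu)
  pts
}

#' @export
print.readout_boot <- function(x, ...) {
  cat(sprintf("bootstrap readout fits (%d resamples)\n", x$n_boot))
  cat("  mean best fit:\n")
  print(round(x$center, 4))
  cat("  SD:\n")
  print(round(sqrt(diag(x$cov)), 4))
  invisible(x)
}
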