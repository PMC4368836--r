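#' Peri-stimulus time histograms
#'
#' Per-neuron, per-stimulus trial-averaged firing rate on a regular bin
#' grid: spike counts averaged over the trials of each stimulus and divided
#' by the bin width. Neurons recorded in several pools are averaged across
#' pools with trial-count weights.
#'
#' @param data a [spike_dataset()].
#' @param delta bin width, seconds (default 0.01).
#' @param pool optional pool id restricting the estimate to one pool.
#' @return an object of class `psth`: list with `m` (array neuron x bin x
#'   stimulus, rate units), `n` (trial counts, neuron x stimulus),
#'   `neurons`, `stimuli`, `mids`, `breaks`, `delta`.
#' @export
estimate_psth <- function(data, delta = 0.01, pool = NULL) {
  stopifnot(inherits(data, "spike_dataset"))
  pools <- if (is.null(pool)) names(data$pools) else as.character(pool)
  stimuli <- stimulus_set(data)$s
  neurons <- sort(unique(unlist(data$pools[pools], use.names = FALSE)))
  binned <- lapply(pools, function(p) .bin_pool(data, p, delta))
  B <- dim(binned[[1]]$R)[3]
  m <- array(0, dim = c(length(neurons), B, length(stimuli)))
  n <- matrix(0L, length(neurons), length(stimuli))
  for (bp in binned) {
    ni <- match(bp$neurons, neurons)
    for (k in seq_along(stimuli)) {
      sel <- bp$trials$s == stimuli[k]
      ns <- sum(sel)
      if (ns == 0L) next
      ms <- colMeans(array(bp$R[sel, , , drop = FALSE],
                           dim = c(ns, length(bp$neurons), B)))
      m[ni, , k] <- m[ni, , k] + ns * ms
      n[ni, k] <- n[ni, k] + ns
    }
  }
  empty <- stimuli[colSums(n) == 0]
  if (length(empty))
    stop("no trials for stimulus value(s): ", paste(empty, collapse = ", "))
  for (k in seq_along(stimuli)) {
    nz <- n[, k] > 0
    m[nz, , k] <- m[nz, , k] / n[nz, k]
  }
  structure(list(m = m, n = n, neurons = neurons, stimuli = stimuli,
                 mids = binned[[1]]$mids, breaks = binned[[1]]$breaks,
                 delta = delta),
            class = "psth")
}

#' Tuning slopes from PSTHs
#'
#' Trial-count-weighted least-squares slope of the PSTH against the stimulus
#' value, per neuron and time bin: \eqn{b_i(t)} in rate units per stimulus
#' unit. Needs at least two distinct stimuli.
#'
#' @param psth a `psth` object from [estimate_psth()].
#' @return matrix neuron x bin of tuning slopes, with the time grid as
#'   attribute `mids`.
#' @export
estimate_tuning <- function(psth) {
  stopifnot(inherits(psth, "psth"))
  s <- psth$stimuli
  if (length(s) < 2L) stop("tuning requires at least 2 distinct stimuli")
  N <- length(psth$neurons); B <- length(psth$mids)
  b <- matrix(0, N, B)
  for (i in seq_len(N)) {
    w <- psth$n[i, ]
    if (sum(w > 0) < 2L) next
    sw <- sum(w); sbar <- sum(w * s) / sw
    denom <- sum(w * (s - sbar)^2)
    b[i, ] <- colSums(w * (s - sbar) * t(psth$m[i, , ])) / denom
  }
  attr(b, "mids") <- psth$mids
  attr(b, "neurons") <- psth$neurons
  b
}

#' Joint peri-stimulus time histogram (noise correlations)
#'
#' Across-trial covariance of the binned rates of pairs of simultaneously
#' recorded neurons, \eqn{C_{ij}(t, u)}: computed per stimulus with the
#' unbiased (n - 1) normalization and then averaged over stimuli with
#' trial-count weights. The JPSTH is assumed stimulus-independent; the
#' maximum across-stimulus deviation is reported as a diagnostic attribute
#' and triggers a warning above `check_threshold`.
#'
#' @inheritParams estimate_psth
#' @param neurons neuron ids to compute the JPSTH for (all pairs). All
#'   requested neurons must share at least one pool.
#' @param check_threshold relative across-stimulus deviation of the
#'   kernel-free summed covariance above which a warning is emitted.
#' @return array `[i, j, t, u]` in rate^2 units with attributes `mids`,
#'   `neurons`, `stim_deviation`.
#' @export
estimate_jpsth <- function(data, delta = 0.01, neurons = NULL,
                           check_threshold = Inf) {
  stopifnot(inherits(data, "spike_dataset"))
  if (is.null(neurons)) neurons <- data$neurons
  holds <- vapply(data$pools, function(p) all(neurons %in% p), logical(1))
  if (!any(holds)) {
    ## identify an offending pair for the error message
    for (i in seq_along(neurons)) for (j in seq_along(neurons)) {
      if (i < j && !any(vapply(data$pools, function(p)
        all(neurons[c(i, j)] %in% p), logical(1))))
        stop("neurons ", neurons[i], " and ", neurons[j],
             " were never recorded together")
    }
    stop("requested neurons share no recording pool")
  }
  use_pools <- names(data$pools)[holds]
  stimuli <- stimulus_set(data)$s
  nn <- length(neurons)
  Cs <- vector("list", length(stimuli))
  ns_tot <- numeric(length(stimuli))
  B <- NULL
  for (p in use_pools) {
    bp <- .bin_pool(data, p, delta)
    ni <- match(neurons, bp$neurons)
    B <- dim(bp$R)[3]
    for (k in seq_along(stimuli)) {
      sel <- bp$trials$s == stimuli[k]
      ns <- sum(sel)
      if (ns < 2L) next
      X <- matrix(bp$R[sel, ni, , drop = FALSE], nrow = ns)  # n x (nn*B)
      Xc <- sweep(X, 2, colMeans(X))
      Ck <- crossprod(Xc) / (ns - 1)                         # (nn*B)^2
      Ck <- array(Ck, dim = c(nn, B, nn, B))
      Ck <- aperm(Ck, c(1, 3, 2, 4))                         # i, j, t, u
      if (is.null(Cs[[k]])) Cs[[k]] <- (ns) * Ck else
        Cs[[k]] <- Cs[[k]] + ns * Ck
      ns_tot[k] <- ns_tot[k] + ns
    }
  }
  if (any(ns_tot == 0))
    stop("need >= 2 trials per stimulus to estimate the JPSTH")
  Cs <- lapply(seq_along(Cs), function(k) Cs[[k]] / ns_tot[k])
  C <- Reduce(`+`, Map(`*`, Cs, ns_tot)) / sum(ns_tot)
  ## stimulus-independence diagnostic on the summed (time-averaged) covariance
  tot <- vapply(Cs, function(x) sum(x) * delta^2, numeric(1))
  dev <- if (sum(abs(tot)) > 0)
    max(abs(tot - mean(tot))) / max(abs(mean(tot)), .Machine$double.eps) else 0
  if (is.finite(check_threshold) && dev > check_threshold)
    warning(sprintf("JPSTH varies across stimuli (relative deviation %.2f)", dev))
  bp0 <- .bin_pool(data, use_pools[1], delta)
  attr(C, "mids") <- bp0$mids
  attr(C, "neurons") <- neurons
  attr(C, "stim_deviation") <- dev
  C
}

#' Choice-covariance (CC) curves
#'
#' The linear analogue of choice probability: per stimulus,
#' \eqn{d_i(t; s) = \psi(s)(1 - \psi(s))\,[E(r_i(t) | s, c=1) - E(r_i(t) | s,
#' c=0)]}, which equals the (1/n) sample covariance between the binned rate
#' and the binary choice. Stimulus groups where all choices agree contribute
#' exactly zero. The stimulus-averaged curve \eqn{d_i(t)} weights each
#' stimulus by its trial count.
#'
#' @inheritParams estimate_psth
#' @return an object of class `cc_curves`: list with `d` (neuron x bin,
#'   stimulus-averaged), `d_s` (neuron x bin x stimulus), `psi` (per-pool
#'   average choice rates are pooled), `neurons`, `stimuli`, `mids`.
#' @export
estimate_cc <- function(data, delta = 0.01, pool = NULL) {
  stopifnot(inherits(data, "spike_dataset"))
  if (all(is.na(data$trials$choice))) stop("dataset has no choices")
  pools <- if (is.null(pool)) names(data$pools) else as.character(pool)
  stimuli <- stimulus_set(data)$s
  neurons <- sort(unique(unlist(data$pools[pools], use.names = FALSE)))
  B <- NULL
  d_s_num <- NULL
  n <- matrix(0, length(neurons), length(stimuli))
  for (p in pools) {
    bp <- .bin_pool(data, p, delta)
    B <- dim(bp$R)[3]
    if (is.null(d_s_num)) d_s_num <- array(0, c(length(neurons), B, length(stimuli)))
    ni <- match(bp$neurons, neurons)
    ch <- bp$trials$choice
    for (k in seq_along(stimuli)) {
      sel <- bp$trials$s == stimuli[k]
      ns <- sum(sel)
      if (ns == 0L) next
      psi <- mean(ch[sel])
      n[ni, k] <- n[ni, k] + ns
      if (psi <= 0 || psi >= 1) next         # sigma_c^2 = 0: contributes 0
      R <- array(bp$R[sel, , , drop = FALSE], c(ns, length(bp$neurons), B))
      m1 <- colMeans(array(R[ch[sel] == 1, , , drop = FALSE],
                           c(sum(ch[sel] == 1), length(bp$neurons), B)))
      m0 <- colMeans(array(R[ch[sel] == 0, , , drop = FALSE],
                           c(sum(ch[sel] == 0), length(bp$neurons), B)))
      d_s_num[ni, , k] <- d_s_num[ni, , k] + ns * psi * (1 - psi) * (m1 - m0)
    }
  }
  d_s <- d_s_num
  for (k in seq_along(stimuli)) {
    nz <- n[, k] > 0
    d_s[nz, , k] <- d_s[nz, , k] / n[nz, k]
  }
  ntot <- rowSums(n)
  d <- matrix(0, length(neurons), B)
  for (k in seq_along(stimuli)) d <- d + d_s[, , k] * (n[, k] / ntot)
  bp0 <- .bin_pool(data, pools[1], delta)
  structure(list(d = d, d_s = d_s, n = n, neurons = neurons,
                 stimuli = stimuli, mids = bp0$mids, breaks = bp0$breaks,
                 delta = delta),
            class = "cc_curves")
}

#' Psychometric curve fit
#'
#' Fits \eqn{\psi(s) = \Phi((s + \mu_d - s_0)/Z)} to the observed choice
#' proportions by trial-count-weighted mean squared error (the default) or
#' by maximum likelihood. `Z` is the just-noticeable difference (JND);
#' `mu_d` the decision bias. With perfect separation at every stimulus the
#' slope is unidentified and `Z` is pinned to a small positive floor with a
#' warning.
#'
#' @param data a [spike_dataset()] with choices.
#' @param method `"mse"` (weighted least squares on proportions, the
#'   default) or `"mle"` (binomial likelihood).
#' @param z_floor lower bound for `Z`, in units of the stimulus range.
#' @return an object of class `psychometry` with elements `Z`, `mu_d`,
#'   `psi` (data.frame `s`, `n`, `psi`), `s0`.
#' @export
fit_psychometric <- function(data, method = c("mse", "mle"),
                             z_floor = 1e-3) {
  stopifnot(inherits(data, "spike_dataset"))
  method <- match.arg(method)
  tr <- data$trials[!is.na(data$trials$choice), , drop = FALSE]
  if (!nrow(tr)) stop("dataset has no choices")
  agg <- aggregate(choice ~ s, tr, mean)
  cnt <- aggregate(choice ~ s, tr, length)
  psi <- data.frame(s = agg$s, n = cnt$choice, psi = agg$choice)
  if (nrow(psi) < 2L) stop("psychometric fit requires >= 2 stimuli")
  s0 <- data$s0
  rng <- max(diff(range(psi$s)), 1e-8)
  floor_Z <- z_floor * rng
  sep <- all(psi$psi %in% c(0, 1))
  ## probit-linearized initial values
  pcl <- pmin(pmax(psi$psi, 1 / (2 * max(psi$n))), 1 - 1 / (2 * max(psi$n)))
  ini <- unname(stats::lm.wfit(cbind(1, psi$s), qnorm(pcl), psi$n)$coefficients)
  Z0 <- if (is.finite(ini[2]) && ini[2] > 1e-12) 1 / ini[2] else rng
  mu0 <- ini[1] * Z0 + s0
  obj <- function(par) {
    Z <- exp(par[1]); mu <- par[2]
    p <- pnorm((psi$s + mu - s0) / Z)
    if (method == "mse") sum(psi$n * (psi$psi - p)^2)
    else {
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(psi$n * (psi$psi * log(p) + (1 - psi$psi) * log(1 - p)))
    }
  }
  fit <- optim(c(log(max(Z0, floor_Z)), unname(mu0)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  Z <- unname(exp(fit$par[1])); mu_d <- unname(fit$par[2])
  if (sep || Z < floor_Z) {
    if (sep) warning("perfect separation at all stimuli; Z pinned to floor")
    Z <- max(Z, floor_Z)
  }
  structure(list(Z = Z, mu_d = mu_d, psi = psi, s0 = s0, method = method,
                 value = fit$value, convergence = fit$convergence),
            class = "psychometry")
}

#' @export
print.psychometry <- function(x, ...) {
  cat(sprintf("psychometric fit (%s): Z = %.4g, mu_d = %.4g (s0 = %g)\n",
              x$method, x$Z, x$mu_d, x$s0))
  print(x$psi, row.names = FALSE)
  invisible(x)
}

#' @export
coef.psychometry <- function(object, ...) {
  c(Z = object$Z, mu_d = object$mu_d)
}

#' Bundle of binned neural statistics
#'
#' Computes PSTH, tuning, CC curves and (optionally, for small neuron sets)
#' the full JPSTH on one common bin grid, as the input to
#' [integrate_statistics()].
#'
#' @inheritParams estimate_psth
#' @param neurons neurons for the JPSTH block (defaults to all; the JPSTH is
#'   quartic in size, so keep this small).
#' @param jpsth logical: compute the JPSTH block?
#' @return an object of class `neural_stats`.
#' @export
neural_stats <- function(data, delta = 0.01, neurons = NULL, jpsth = TRUE) {
  ps <- estimate_psth(data, delta)
  b <- estimate_tuning(ps)
  cc <- if (!all(is.na(data$trials$choice))) estimate_cc(data, delta) else NULL
  C <- if (jpsth) estimate_jpsth(data, delta, neurons = neurons) else NULL
  s <- data$trials$s
  structure(list(psth = ps, b = b, cc = cc, C = C,
                 mids = ps$mids, breaks = ps$breaks, delta = delta,
                 stimuli = ps$stimuli, n_s = stimulus_set(data)$n,
                 sigma_s2 = mean(s^2) - mean(s)^2, s0 = data$s0),
            class = "neural_stats")
}

#' Kernel-integrated statistics from binned statistics
#'
#' Quadrature of the binned statistics against the discretized kernel:
#' \eqn{\bar b_i = \int b_i(t) k(t) dt}, \eqn{\bar C_{ij}(t) = \int
#' C_{ij}(t, u) k(u) du}, \eqn{\bar{\bar C}_{ij} = \int \bar C_{ij}(t) k(t)
#' dt} (symmetrized), \eqn{\bar d_i = \int d_i(t) k(t) dt}. These are the
#' tuning vector, once- and doubly-integrated noise covariance, and choice
#' covariance of the integrated spike counts.
#'
#' @param stats a [neural_stats()] object (JPSTH block required for the
#'   covariance parts).
#' @param kernel a [temporal_kernel()].
#' @return an object of class `integrated_stats` with `bbar`, `Cbar`
#'   (neuron x neuron x bin), `Cbb`, `dbar`, `sigma_s2`, `kernel`.
#' @export
integrate_statistics <- function(stats, kernel) {
  stopifnot(inherits(stats, "neural_stats"), inherits(kernel, "temporal_kernel"))
  kw <- kernel_weights(kernel, stats$breaks)
  full_mass <- if (kernel$shape == "square")
    min(kernel$t_R, kernel$w) / kernel$w else 1 - exp(-kernel$t_R / kernel$w)
  if (sum(kw) < 1e-12)
    stop("kernel support lies entirely outside the recorded window")
  if (sum(kw) < full_mass - 1e-6)
    warning("kernel support truncated by the recorded window")
  if (is.null(stats$C))
    stop("integrate_statistics needs the JPSTH block (neural_stats(jpsth = TRUE))")
  neurons <- attr(stats$C, "neurons")
  ni <- match(neurons, attr(stats$b, "neurons"))
  bbar <- as.numeric(stats$b[ni, , drop = FALSE] %*% kw)
  nn <- length(neurons); B <- length(stats$mids)
  ## Cbar[i, j, t] = sum_u C[i, j, t, u] * kw[u]
  Cm <- matrix(stats$C, nrow = nn * nn * B)   # (i,j,t) x u
  Cbar <- array(Cm %*% kw, dim = c(nn, nn, B))
  Cbb <- matrix(matrix(Cbar, nrow = nn * nn) %*% kw, nn, nn)
  Cbb <- (Cbb + t(Cbb)) / 2
  dbar <- if (!is.null(stats$cc)) {
    di <- match(neurons, stats$cc$neurons)
    as.numeric(stats$cc$d[di, , drop = FALSE] %*% kw)
  } else NULL
  structure(list(bbar = bbar, Cbar = Cbar, Cbb = Cbb, dbar = dbar,
                 sigma_s2 = stats$sigma_s2, kernel = kernel,
                 neurons = neurons, mids = stats$mids, delta = stats$delta,
                 s0 = stats$s0, stimuli = stats$stimuli, n_s = stats$n_s),
            class = "integrated_stats")
}

#' Kernel-integrated statistics computed directly from spike counts
#'
#' The direct route to the same quantities as [integrate_statistics()]:
#' integrates each trial's spike trains through the kernel
#' ([integrate_trial()]) and computes the tuning, covariance and choice
#' covariance of the resulting counts \eqn{\bar r}. Agrees with the
#' quadrature route up to binning error (exactly, for a square kernel
#' aligned with the bin grid).
#'
#' @param data a [spike_dataset()].
#' @param kernel a [temporal_kernel()].
#' @param delta bin width for the time-resolved part `Cbar`, seconds.
#' @param pool pool id (statistics need simultaneous recordings; defaults to
#'   the first pool).
#' @return an `integrated_stats` object (same contract as
#'   [integrate_statistics()]).
#' @export
integrated_statistics <- function(data, kernel, delta = 0.01, pool = NULL) {
  stopifnot(inherits(data, "spike_dataset"))
  if (is.null(pool)) pool <- names(data$pools)[1]
  bp <- .bin_pool(data, pool, delta)
  kw <- kernel_weights(kernel, bp$breaks)
  n <- nrow(bp$trials); N <- length(bp$neurons); B <- dim(bp$R)[3]
  rbar <- matrix(matrix(bp$R, nrow = n * N) %*% kw, n, N)
  s <- bp$trials$s
  ## tuning: trial-weighted regression of group means on s
  st <- sort(unique(s))
  gm <- t(matrix(vapply(st, function(v)
    colMeans(rbar[s == v, , drop = FALSE]), numeric(N)), nrow = N))
  ns <- vapply(st, function(v) sum(s == v), numeric(1))
  sbar <- sum(ns * st) / sum(ns)
  bbar <- colSums(ns * (st - sbar) * gm) / sum(ns * (st - sbar)^2)
  ## pooled within-stimulus covariance, unbiased per group
  rc <- .center_by_stim(rbar, s)
  denom <- attr(rc, "denom")
  Cbb <- crossprod(rc) / denom
  Cbb <- (Cbb + t(Cbb)) / 2
  ## Cbar[i, j, t] = Cov[r_i(t), rbar_j | s]
  Rc <- .center_by_stim(bp$R, s)
  Rm <- matrix(Rc, nrow = n)                       # n x (N*B), (neuron, bin)
  CB <- crossprod(Rm, rc) / denom                  # (N*B) x N  -> [i, t, j]
  Cbar <- aperm(array(CB, dim = c(N, B, N)), c(1, 3, 2))
  ## dbar: E_s[ Cov(rbar_i, c | s) ] with 1/n_s convention, weights n_s
  dbar <- NULL
  ch <- bp$trials$choice
  if (!all(is.na(ch))) {
    dbar <- numeric(N)
    for (v in st) {
      sel <- s == v
      cc <- ch[sel]
      dv <- colMeans(rbar[sel, , drop = FALSE] * cc) -
        colMeans(rbar[sel, , drop = FALSE]) * mean(cc)
      dbar <- dbar + sum(sel) / n * dv
    }
  }
  structure(list(bbar = as.numeric(bbar), Cbar = Cbar, Cbb = Cbb,
                 dbar = dbar, sigma_s2 = mean(s^2) - mean(s)^2,
                 kernel = kernel, neurons = bp$neurons, mids = bp$mids,
                 delta = delta, s0 = data$s0, stimuli = st, n_s = ns,
                 rbar = rbar, trials = bp$trials),
            class = "integrated_stats")
}

#' @export
print.integrated_stats <- function(x, ...) {
  cat(sprintf("integrated statistics: %d neurons, %s kernel (w = %g ms, t_R = %g ms)\n",
              length(x$neurons), x$kernel$shape,
              1e3 * x$kernel$w, 1e3 * x$kernel$t_R))
  cat(sprintf("  |bbar| = %.4g, tr(Cbb)/N = %.4g, sigma_s^2 = %.4g\n",
              sqrt(sum(x$bbar^2)), mean(diag(x$Cbb)), x$sigma_s2))
  invisible(x)
}
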