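#' Trial-structured spike dataset
#'
#' The universal input container: spike events with per-trial stimulus and
#' choice labels, plus the recording-pool bookkeeping. A *pool* is a set of
#' simultaneously recorded neurons; every trial belongs to exactly one pool
#' and records exactly that pool's neurons. Choices may be missing (`NA`)
#' for datasets whose behavior has not been generated yet; any other binary
#' coding is remapped to \{0, 1\} on ingest.
#'
#' @param spikes data.frame with columns `trial`, `neuron`, `time` (seconds,
#'   in `[0, T]`).
#' @param trials data.frame with columns `trial`, `s` (stimulus value),
#'   `choice` (0/1 or `NA`), `pool`.
#' @param pools named list mapping pool id to the integer vector of neuron
#'   ids recorded in that pool. Defaults to a single pool containing all
#'   neurons referenced anywhere.
#' @param T trial duration, seconds.
#' @param s0 task threshold stimulus.
#' @param n_total size of the full neural population the pools are sampled
#'   from (defaults to the number of distinct neurons across pools). Used as
#'   the mixing denominator \eqn{p = K/N_{tot}} in population averages.
#' @return an object of class `spike_dataset`.
#' @export
spike_dataset <- function(spikes, trials, pools = NULL, T, s0,
                          n_total = NULL) {
  stopifnot(is.data.frame(spikes), is.data.frame(trials))
  need <- c("trial", "neuron", "time")
  if (!all(need %in% names(spikes)))
    stop("'spikes' must have columns trial, neuron, time")
  if (!all(c("trial", "s", "choice") %in% names(trials)))
    stop("'trials' must have columns trial, s, choice")
  if (!is.numeric(T) || T <= 0) stop("'T' must be a positive duration")
  spikes <- spikes[need]
  spikes$trial <- as.integer(spikes$trial)
  spikes$neuron <- as.integer(spikes$neuron)
  if (any(spikes$time < 0 | spikes$time > T))
    stop("spike times must lie in [0, T]")
  if (is.null(trials$pool)) trials$pool <- 1L
  trials <- trials[c("trial", "s", "choice", "pool")]
  trials$trial <- as.integer(trials$trial)
  if (anyDuplicated(trials$trial)) stop("duplicated trial ids in 'trials'")
  ## remap any binary coding to {0, 1}
  ch <- trials$choice
  vals <- sort(unique(ch[!is.na(ch)]))
  if (length(vals) > 2L) stop("choices must be binary")
  if (length(vals) && !all(vals %in% c(0, 1))) {
    trials$choice <- as.integer(match(ch, vals) - 1L)
    message("choices remapped to {0, 1}: ", vals[1], " -> 0, ",
            vals[length(vals)], " -> 1")
  }
  if (is.null(pools)) {
    ids <- sort(unique(c(spikes$neuron, integer(0))))
    if (!length(ids)) ids <- 1L
    pools <- stats::setNames(list(as.integer(ids)),
                             as.character(unique(trials$pool)[1]))
    trials$pool <- names(pools)[1]
  }
  trials$pool <- as.character(trials$pool)
  pools <- lapply(pools, as.integer)
  if (is.null(names(pools)) || any(names(pools) == ""))
    names(pools) <- as.character(seq_along(pools))
  bad <- setdiff(trials$pool, names(pools))
  if (length(bad))
    stop("trial references unknown pool: ", paste(bad, collapse = ", "))
  if (any(!spikes$trial %in% trials$trial))
    stop("spike references unknown trial id")
  ## each spike must come from a neuron of its trial's pool
  pool_of <- stats::setNames(trials$pool, trials$trial)
  sp_pool <- pool_of[as.character(spikes$trial)]
  for (p in unique(sp_pool)) {
    sel <- sp_pool == p
    if (any(!spikes$neuron[sel] %in% pools[[p]]))
      stop("spikes from neurons outside the pool of their trial (pool ", p, ")")
  }
  all_neurons <- sort(unique(unlist(pools, use.names = FALSE)))
  if (is.null(n_total)) n_total <- length(all_neurons)
  if (n_total < length(all_neurons))
    stop("'n_total' smaller than the number of distinct recorded neurons")
  structure(list(spikes = spikes, trials = trials, pools = pools,
                 T = T, s0 = s0, n_total = as.integer(n_total),
                 neurons = all_neurons),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  ss <- stimulus_set(x)
  cat(sprintf("spike_dataset: %d trials, %d pools, %d distinct neurons (N_tot = %d)\n",
              nrow(x$trials), length(x$pools), length(x$neurons), x$n_total))
  cat(sprintf("  T = %g s, s0 = %g; stimuli: %s\n", x$T, x$s0,
              paste(sprintf("%g (n=%d)", ss$s, ss$n), collapse = ", ")))
  cat(sprintf("  %d spikes; choices %s\n", nrow(x$spikes),
              if (all(is.na(x$trials$choice))) "absent" else "present"))
  invisible(x)
}

#' Distinct stimulus values and their trial counts
#' @param data a [spike_dataset()].
#' @return data.frame with columns `s`, `n`.
#' @export
stimulus_set <- function(data) {
  stopifnot(inherits(data, "spike_dataset"))
  tab <- table(data$trials$s)
  data.frame(s = as.numeric(names(tab)), n = as.integer(tab))
}

## Binned rates of one pool: array [trial, neuron, bin] in rate units.
## Returns trial/neuron indices alongside; the workhorse behind all
## estimation routines.
.bin_pool <- function(data, pool, delta) {
  tr <- data$trials[data$trials$pool == pool, , drop = FALSE]
  nid <- data$pools[[pool]]
  breaks <- seq(0, data$T, by = delta)
  if (abs(tail(breaks, 1) - data$T) > 1e-12) breaks <- c(breaks, data$T)
  B <- length(breaks) - 1L
  sp <- data$spikes[data$spikes$trial %in% tr$trial, , drop = FALSE]
  n <- nrow(tr); N <- length(nid)
  arr <- array(0, dim = c(n, N, B))
  if (nrow(sp)) {
    ti <- match(sp$trial, tr$trial)
    ni <- match(sp$neuron, nid)
    bi <- findInterval(sp$time, breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    idx <- (bi - 1L) * (n * N) + (ni - 1L) * n + ti
    arr <- array(tabulate(idx, nbins = n * N * B), dim = c(n, N, B))
  }
  widths <- diff(breaks)
  arr <- sweep(arr, 3, widths, "/")
  list(R = arr, trials = tr, neurons = nid, breaks = breaks, delta = delta,
       mids = (head(breaks, -1) + tail(breaks, -1)) / 2)
}

## center an [n, N] or [n, N, B] array within stimulus groups; returns the
## centered array plus the pooled-covariance denominator (n - #groups)
.center_by_stim <- function(x, s) {
  d <- dim(x); n <- d[1]
  groups <- split(seq_len(n), s)
  if (length(d) == 2L) {
    for (idx in groups)
      x[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                        colMeans(x[idx, , drop = FALSE]))
  } else {
    m <- matrix(x, nrow = n)
    for (idx in groups)
      m[idx, ] <- sweep(m[idx, , drop = FALSE], 2,
                        colMeans(m[idx, , drop = FALSE]))
    x <- array(m, dim = d)
  }
  attr(x, "denom") <- n - length(groups)
  x
}

#' Write / read a spike dataset as plain-text files
#'
#' Persists a dataset losslessly as a directory of CSV tables
#' (`spikes.csv`, `trials.csv`, `pools.csv`) plus a JSON metadata file
#' (`meta.json` with `T`, `s0`, `n_total`). Times are stored in seconds at
#' full double precision.
#'
#' @param data a [spike_dataset()].
#' @param path directory to write to / read from (created if needed).
#' @return `write_spike_dataset` returns `path` invisibly;
#'   `read_spike_dataset` returns the reconstructed [spike_dataset()].
#' @export
write_spike_dataset <- function(data, path) {
  stopifnot(inherits(data, "spike_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) write.csv(df, file.path(path, f), row.names = FALSE)
  wcsv(data$spikes, "spikes.csv")
  wcsv(data$trials, "trials.csv")
  pools_df <- do.call(rbind, lapply(names(data$pools), function(p)
    data.frame(pool = p, neuron = data$pools[[p]])))
  wcsv(pools_df, "pools.csv")
  jsonlite::write_json(list(T = data$T, s0 = data$s0, n_total = data$n_total),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_dataset
#' @export
read_spike_dataset <- function(path) {
  req <- file.path(path, c("spikes.csv", "trials.csv", "pools.csv", "meta.json"))
  miss <- req[!file.exists(req)]
  if (length(miss)) stop("missing dataset files: ", paste(miss, collapse = ", "))
  spikes <- read.csv(req[1])
  trials <- read.csv(req[2])
  pools_df <- read.csv(req[3], colClasses = c(pool = "character"))
  meta <- jsonlite::read_json(req[4], simplifyVector = TRUE)
  pools <- split(pools_df$neuron, pools_df$pool)
  spike_dataset(spikes, trials, pools = pools, T = meta$T, s0 = meta$s0,
                n_total = meta$n_total)
}

#' Build a dataset from a flat event list
#'
#' Imports a CSV-style event list (columns `trial`, `neuron`, `time`) and a
#' trial table into a validated [spike_dataset()]; the same schema checks
#' apply as for the native reader.
#'
#' @param events data.frame (or path to a CSV file) with columns `trial`,
#'   `neuron`, `time`.
#' @param trials data.frame with columns `trial`, `s`, `choice` (and
#'   optionally `pool`).
#' @inheritParams spike_dataset
#' @return a [spike_dataset()].
#' @export
as_spike_dataset <- function(events, trials, pools = NULL, T, s0,
                             n_total = NULL) {
  if (is.character(events)) events <- read.csv(events)
  spike_dataset(events, trials, pools = pools, T = T, s0 = s0,
                n_total = n_total)
}

#' Bootstrap-resample the trials of a dataset
#'
#' Trial-level resampling with replacement, stratified within each
#' (pool, stimulus) cell so the design balance is preserved. Resampled
#' trials get fresh ids; spikes are duplicated accordingly.
#'
#' @param data a [spike_dataset()].
#' @return a new [spike_dataset()] of the same size.
#' @export
resample_trials <- function(data) {
  stopifnot(inherits(data, "spike_dataset"))
  tr <- data$trials
  cell <- interaction(tr$pool, tr$s, drop = TRUE)
  picked <- unlist(lapply(split(seq_len(nrow(tr)), cell), function(idx)
    idx[sample.int(length(idx), length(idx), replace = TRUE)]),
    use.names = FALSE)
  new_tr <- tr[picked, , drop = FALSE]
  old_id <- new_tr$trial
  new_tr$trial <- seq_along(picked)
  sp_by_trial <- split(seq_len(nrow(data$spikes)), data$spikes$trial)
  sp_idx <- sp_by_trial[as.character(old_id)]
  reps <- lengths(sp_idx); reps[is.na(names(sp_idx))] <- 0L
  sp <- data$spikes[unlist(sp_idx, use.names = FALSE), , drop = FALSE]
  sp$trial <- rep(new_tr$trial, reps)
  rownames(sp) <- rownames(new_tr) <- NULL
  spike_dataset(sp, new_tr, pools = data$pools, T = data$T, s0 = data$s0,
                n_total = data$n_total)
}
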