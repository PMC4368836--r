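#' Temporal integration kernel
#'
#' The readout integrates each spike train through a causal kernel
#' \eqn{k(t)} supported on \eqn{[\max(0, t_R - w),\, t_R]}: `w` is the
#' duration of temporal integration and `t_R` the extraction time at which
#' the percept is read out. The square kernel has constant height \eqn{1/w};
#' the exponential kernel decays backwards in time from \eqn{t_R} with time
#' constant `w`, i.e. \eqn{k(t) = \exp(-(t_R - t)/w)/w} for \eqn{t \le t_R}.
#' When `t_R < w` the kernel is truncated at 0 and deliberately *not*
#' renormalized: integration starts at stimulus onset.
#'
#' @param shape `"square"` (default) or `"exponential"`.
#' @param w integration window, seconds, > 0.
#' @param t_R extraction time, seconds, > 0.
#' @return an object of class `temporal_kernel`.
#' @examples
#' k <- temporal_kernel("square", w = 0.05, t_R = 0.10)
#' kernel_weights(k, seq(0, 0.2, by = 0.01))
#' @export
temporal_kernel <- function(shape = c("square", "exponential"), w, t_R) {
  shape <- match.arg(shape)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0)
    stop("'w' must be a positive duration in seconds")
  if (!is.numeric(t_R) || length(t_R) != 1L || !is.finite(t_R) || t_R <= 0)
    stop("'t_R' must be a positive time in seconds")
  structure(list(shape = shape, w = w, t_R = t_R), class = "temporal_kernel")
}

#' @export
print.temporal_kernel <- function(x, ...) {
  cat(sprintf("temporal kernel: %s, w = %g ms, t_R = %g ms\n",
              x$shape, 1e3 * x$w, 1e3 * x$t_R))
  invisible(x)
}

## continuous kernel density k(t)
.kernel_density <- function(kernel, t) {
  with(kernel, switch(shape,
    square      = ifelse(t >= max(0, t_R - w) & t <= t_R, 1 / w, 0),
    exponential = ifelse(t >= 0 & t <= t_R, exp(-(t_R - t) / w) / w, 0)
  ))
}

#' Discretize a temporal kernel on a bin grid
#'
#' Integrates the kernel density over each bin of a time grid, giving the
#' quadrature weights used to turn binned statistics (PSTH, tuning, JPSTH,
#' choice covariance) into their kernel-integrated forms. For binned *rates*
#' the integrated quantity is `sum(rate * weights)`. An untruncated kernel
#' has total weight 1 (`sum(weights) == 1`); a kernel truncated at time 0 is
#' not renormalized.
#'
#' @param kernel a [temporal_kernel()].
#' @param breaks ordered vector of bin edges, seconds.
#' @return numeric vector of per-bin weights (`length(breaks) - 1`).
#' @export
kernel_weights <- function(kernel, breaks) {
  stopifnot(inherits(kernel, "temporal_kernel"))
  if (length(breaks) < 2L || is.unsorted(breaks, strictly = TRUE))
    stop("'breaks' must be strictly increasing bin edges")
  lo <- head(breaks, -1L); hi <- tail(breaks, -1L)
  with(kernel, {
    if (shape == "square") {
      a <- max(0, t_R - w)
      pmax(0, pmin(hi, t_R) - pmax(lo, a)) / w
    } else {
      ## closed-form integral of exp(-(t_R - t)/w)/w over [lo, hi] clipped to [0, t_R]
      l <- pmax(lo, 0); h <- pmin(hi, t_R)
      out <- exp(-(t_R - h) / w) - exp(-(t_R - l) / w)
      out[h <= l] <- 0
      out
    }
  })
}

#' Kernel-integrated activity of a single trial
#'
#' Computes \eqn{\bar r_i = \sum_{\rm spikes} k(t_{\rm spike})} for one
#' neuron, in rate units. For a square kernel this is exactly the spike count
#' inside \eqn{[\max(0, t_R - w), t_R]} divided by `w`. Empty spike trains
#' are valid and give 0.
#'
#' @param spike_times numeric vector of spike times (seconds), or a list of
#'   such vectors (one per neuron).
#' @param kernel a [temporal_kernel()].
#' @return a numeric scalar (or vector, for a list input) of integrated
#'   activity in rate units.
#' @export
integrate_trial <- function(spike_times, kernel) {
  stopifnot(inherits(kernel, "temporal_kernel"))
  if (is.list(spike_times))
    return(vapply(spike_times, integrate_trial, numeric(1), kernel = kernel))
  if (length(spike_times) == 0L) return(0)
  sum(.kernel_density(kernel, spike_times))
}
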