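#' Canonical double-gamma hemodynamic response function
#'
#' The BOLD impulse response is modelled as the difference of two gamma
#' densities: a positive lobe peaking about 5 s after the event and a delayed
#' undershoot, the parametrization used throughout event-related fMRI
#' modelling. The response is causal (`hrf(t) = 0` for `t <= 0`) and is
#' scaled so its peak amplitude equals 1, making pattern amplitudes in the
#' simulator directly interpretable as peak signal change.
#'
#' @param t numeric vector of times in seconds relative to the event onset.
#' @param peak_delay shape of the positive gamma lobe (seconds; with
#'   `dispersion = 1` the lobe peaks near `peak_delay - 1`).
#' @param undershoot_delay shape of the undershoot lobe (seconds).
#' @param dispersion,u_dispersion scale (dispersion) of the two lobes, seconds.
#' @param ratio relative amplitude of the undershoot.
#' @return numeric vector of unitless amplitudes, peak normalized to 1.
#' @examples
#' t <- seq(0, 30, by = 0.5)
#' h <- hrf(t)
#' t[which.max(h)]  # ~5 s
#' @export
hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                dispersion = 1, u_dispersion = 1, ratio = 1/6) {
  if (peak_delay <= 0 || undershoot_delay <= 0 ||
      dispersion <= 0 || u_dispersion <= 0 || ratio < 0)
    stop("invalid HRF shape parameters: delays and dispersions must be positive, ratio non-negative")
  raw <- function(tt) {
    out <- numeric(length(tt))
    pos <- tt > 0
    out[pos] <- stats::dgamma(tt[pos], shape = peak_delay / dispersion,
                              rate = 1 / dispersion) -
      ratio * stats::dgamma(tt[pos], shape = undershoot_delay / u_dispersion,
                            rate = 1 / u_dispersion)
    out
  }
  # peak amplitude for normalization: locate the global maximum on a grid,
  # then refine locally (a plain 1D optimize over the whole support can be
  # trapped by the undershoot lobe)
  tmax <- (peak_delay + undershoot_delay) * max(dispersion, u_dispersion)
  grid <- seq(0, tmax, length.out = 2048)
  i <- which.max(raw(grid))
  pk <- stats::optimize(raw, c(grid[max(1L, i - 1L)],
                               grid[min(length(grid), i + 1L)]),
                        maximum = TRUE, tol = 1e-10)
  if (!is.finite(pk$objective) || pk$objective <= 0)
    stop("invalid HRF shape parameters: response has no positive peak")
  raw(t) / pk$objective
}
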