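# Broad- vs narrow-spiking classification from mean extracellular waveforms.
# Spikes are aligned on the trough, averaged, spline-interpolated, and the
# width of the post-trough positive peak at half of its maximum separates
# putative excitatory (broad) from putative inhibitory (narrow) units at
# 0.35 ms.

#' Synthetic mean-waveform template
#'
#' Difference-of-Gaussians extracellular waveform: a negative trough followed
#' by a positive repolarization peak whose full width at half maximum is
#' 0.5 ms (broad) or 0.2 ms (narrow). Sampled at 1/30 ms (30 kHz).
#'
#' @param kind `"broad"` or `"narrow"`.
#' @param dt_ms Sampling interval (ms).
#' @param peak_fwhm_ms Optional explicit peak FWHM, overriding `kind`.
#' @return List of class `waveform_template`: samples, dt_ms, t_ms.
#' @export
waveform_template <- function(kind = c("broad", "narrow"), dt_ms = 1 / 30,
                              peak_fwhm_ms = NULL) {
  kind <- match.arg(kind)
  if (is.null(peak_fwhm_ms)) {
    peak_fwhm_ms <- if (kind == "broad") 0.5 else 0.2
  }
  sigma_pk <- peak_fwhm_ms / (2 * sqrt(2 * log(2)))
  t <- seq(0, 3, by = dt_ms)
  trough_at <- 0.8
  peak_at <- trough_at + max(0.35, 3 * sigma_pk)
  w <- -exp(-(t - trough_at)^2 / (2 * 0.06^2)) +
    0.5 * exp(-(t - peak_at)^2 / (2 * sigma_pk^2))
  structure(list(samples = w, dt_ms = dt_ms, t_ms = t),
            class = "waveform_template")
}

#' Trough-aligned average waveform
#'
#' Shifts every spike waveform so the troughs (global minima) coincide,
#' averages over the overlapping support, and interpolates the average with a
#' cubic spline to a finer grid.
#'
#' @param spike_waveforms Matrix, one waveform per row (equal lengths).
#' @param dt_ms Raw sampling interval (ms).
#' @param interp_factor Interpolation factor (default 10: output grid is
#'   `dt_ms / 10`).
#' @return List of class `waveform_template` (samples on the interpolated
#'   grid, dt_ms of that grid, t_ms, trough_index).
#' @export
average_aligned_waveform <- function(spike_waveforms, dt_ms = 1 / 30,
                                     interp_factor = 10) {
  if (is.vector(spike_waveforms)) {
    spike_waveforms <- matrix(spike_waveforms, nrow = 1)
  }
  if (nrow(spike_waveforms) < 1) stop("need at least one waveform")
  rng <- apply(spike_waveforms, 1, function(w) diff(range(w)))
  if (any(rng == 0)) stop("flat waveform: no trough to align on")
  troughs <- apply(spike_waveforms, 1, which.min)
  ref <- stats::median(troughs)
  ns <- ncol(spike_waveforms)
  # Overlap support common to all shifted waveforms.
  shift <- troughs - ref
  lo <- 1 + max(shift)
  hi <- ns + min(shift)
  if (hi <= lo) stop("waveform troughs too dispersed: no overlap support")
  idx <- lo:hi
  aligned <- t(vapply(seq_len(nrow(spike_waveforms)),
                      function(i) spike_waveforms[i, idx + shift[i]],
                      numeric(length(idx))))
  avg <- colMeans(aligned)
  t_raw <- (idx - 1) * dt_ms
  t_fine <- seq(t_raw[1], t_raw[length(t_raw)], by = dt_ms / interp_factor)
  sp <- stats::spline(t_raw, avg, xout = t_fine, method = "fmm")
  structure(
    list(samples = sp$y, dt_ms = dt_ms / interp_factor, t_ms = t_fine,
         trough_index = which.min(sp$y)),
    class = "waveform_template")
}

#' Width of the post-trough peak at half maximum
#'
#' Locates the maximum after the trough and measures the width between the
#' two half-maximum crossings (linear interpolation between samples).
#' Amplitude is taken relative to zero.
#'
#' @param template A `waveform_template` (or list with `samples`, `dt_ms`).
#' @return List: width_ms (`NA` with a reason when the peak does not return
#'   to half maximum within the record), peak_amplitude, reason.
#' @export
peak_half_width <- function(template) {
  w <- template$samples
  dt <- template$dt_ms
  i0 <- which.min(w)
  post <- w[i0:length(w)]
  ipk <- which.max(post)
  peak <- post[ipk]
  if (peak <= 0) {
    return(list(width_ms = NA_real_, peak_amplitude = peak,
                reason = "no_positive_peak"))
  }
  half <- peak / 2
  cross_left <- function() {
    for (j in seq(ipk - 1, 1)) {
      if (post[j] < half) {
        return(j + (half - post[j]) / (post[j + 1] - post[j]))
      }
    }
    NA_real_
  }
  cross_right <- function() {
    if (ipk == length(post)) return(NA_real_)
    for (j in seq(ipk + 1, length(post))) {
      if (post[j] < half) {
        return(j - 1 + (post[j - 1] - half) / (post[j - 1] - post[j]))
      }
    }
    NA_real_
  }
  xl <- if (ipk > 1) cross_left() else NA_real_
  xr <- cross_right()
  if (is.na(xl) || is.na(xr)) {
    return(list(width_ms = NA_real_, peak_amplitude = peak,
                reason = "peak_does_not_return_to_half_max"))
  }
  list(width_ms = (xr - xl) * dt, peak_amplitude = peak, reason = "ok")
}

#' Broad/narrow cell-type classification
#'
#' Narrow-spiking (putative inhibitory) when the peak half-width is strictly
#' below the threshold; broad-spiking (putative excitatory) otherwise,
#' including a width exactly at the threshold.
#'
#' @param width_ms Peak width at half maximum (ms).
#' @param threshold_ms Classification threshold (default 0.35 ms).
#' @return `"narrow"` or `"broad"`.
#' @export
classify_cell_type <- function(width_ms, threshold_ms = 0.35) {
  if (is.na(width_ms)) stop("width_ms is undefined")
  if (width_ms < threshold_ms) "narrow" else "broad"
}
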