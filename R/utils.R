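# Internal helpers shared across modules.

# Count spikes in half-open windows [a, b). `spikes` must be sorted.
# Vectorized over a/b.
n_spikes_in <- function(spikes, a, b) {
  findInterval(b, spikes, left.open = TRUE) -
    findInterval(a, spikes, left.open = TRUE)
}

# Per-event firing rate in a window relative to each event time.
#' Per-event firing rate in a fixed window
#'
#' Counts spikes in the half-open window \code{[event + window[1],
#' event + window[2])} for every event and divides by the window length.
#'
#' @param spikes Sorted numeric vector of spike times (s, session clock).
#' @param event_times Numeric vector of alignment times (s, session clock).
#' @param window Length-2 numeric, window relative to each event in seconds;
#'   half-open \code{[t0, t1)}, \code{t1 > t0}.
#' @return Numeric vector of rates (spikes/s), one per event.
#' @export
event_window_rate <- function(spikes, event_times, window) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) stop("window must satisfy t1 > t0")
  if (is.unsorted(spikes)) spikes <- sort(spikes)
  n <- n_spikes_in(spikes, event_times + window[1], event_times + window[2])
  n / (window[2] - window[1])
}

# Wilcoxon wrapper that maps degenerate inputs (all-tied pairs, empty) to NA
# instead of an error.
safe_wilcox_p <- function(x, y = NULL, paired = FALSE,
                          alternative = "two.sided") {
  p <- tryCatch(
    suppressWarnings(
      stats::wilcox.test(x, y, paired = paired,
                         alternative = alternative)$p.value
    ),
    error = function(e) NA_real_
  )
  if (!is.null(p) && !is.na(p) && is.nan(p)) p <- NA_real_
  p
}

# One-sample / paired t-test p that tolerates zero-variance input: a constant
# nonzero difference is unambiguous evidence (p -> 0), a constant zero
# difference is no evidence (p -> 1).
safe_t_p <- function(diffs, alternative = "two.sided") {
  if (length(diffs) < 2) return(NA_real_)
  if (stats::sd(diffs) == 0) {
    return(if (mean(diffs) == 0) 1 else 0)
  }
  stats::t.test(diffs, alternative = alternative)$p.value
}

# Gaussian smoothing of a regularly sampled series (reflected edges).
gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_along(x)]
}

assert_prob <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single finite probability in [0, 1]", name))
  }
  invisible(x)
}

assert_pos <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("%s must be a single positive finite number", name))
  }
  invisible(x)
}
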