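# Optogenetic phototagging. A unit counts as opsin-expressing when (i) a
# stimulus-associated spike-latency test (SALT) finds that first-spike
# latency distributions after laser onset differ from pre-laser baseline
# epochs (P < 0.01) and (ii) the waveforms of laser-evoked spikes correlate
# with spontaneous-spike waveforms (Pearson r > 0.9). The evoked-response
# latency is then read off a 0.1-ms PSTH via per-bin t-tests against the
# pre-laser rate.

# First-spike latency histogram per epoch: one latency per (pulse, epoch),
# pooled over pulses; a trailing overflow bin holds "no spike in epoch".
latency_histograms <- function(spikes, starts_mat, win_s, bin_s) {
  n_bins <- as.integer(round(win_s / bin_s))
  starts <- as.vector(starts_mat)
  fi <- findInterval(starts, spikes, left.open = TRUE)
  idx <- fi + 1L
  lat <- rep(Inf, length(starts))
  ok <- idx <= length(spikes)
  lat[ok] <- spikes[idx[ok]] - starts[ok]
  b <- ifelse(lat < win_s,
              pmin(floor(lat / bin_s + 1e-9) + 1L, n_bins), n_bins + 1L)
  bm <- matrix(b, nrow = nrow(starts_mat))
  t(apply(bm, 2, tabulate, nbins = n_bins + 1L))
}

# Pairwise Jensen-Shannon divergences (base-2) among histogram rows; returns
# per-row median divergence to all other rows.
median_js_to_others <- function(hist_counts, eps = 1e-9) {
  p <- hist_counts + eps
  p <- p / rowSums(p)
  ent <- function(m) -rowSums(m * log2(m))
  h <- ent(p)
  m <- nrow(p)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    j <- (i + 1):m
    mid <- (p[j, , drop = FALSE] +
              matrix(p[i, ], length(j), ncol(p), byrow = TRUE)) / 2
    dij <- ent(mid) - (h[j] + h[i]) / 2
    d[i, j] <- dij
    d[j, i] <- dij
  }
  vapply(seq_len(m), function(i) stats::median(d[i, -i]), 0)
}

#' Stimulus-associated spike-latency test (SALT) p-value
#'
#' For each laser pulse, first-spike latencies are collected in the post-laser
#' test epoch and in `n_baseline_epochs` contiguous same-length epochs carved
#' from the `baseline_span_ms` preceding the pulse. Latencies are pooled over
#' pulses into per-epoch histograms (1-ms bins plus an explicit no-spike
#' overflow bin). All pairwise Jensen-Shannon divergences among epoch
#' histograms are computed; each epoch is scored by its median divergence to
#' the others. Under the null the test epoch is exchangeable with the
#' baseline epochs, so the rank of its score is uniform and
#' `p = (1 + #\{baseline scores >= test score\}) / (n_baseline_epochs + 1)`
#' is an exact p-value.
#'
#' @param spike_times Sorted spike times (s).
#' @param laser_times Sorted pulse-onset times (s); at least 50 pulses.
#' @param test_window_ms Post-laser test-epoch length (default 10 ms, the
#'   tagging window).
#' @param baseline_span_ms Pre-laser span carved into baseline epochs
#'   (default 1000 ms; must fit before the first pulse and between pulses).
#' @param n_baseline_epochs Number of baseline epochs (default 100, giving a
#'   p-value resolution of 1/101).
#' @param bin_ms Latency-histogram bin (default 1 ms).
#' @return List: p (in (0, 1\]; `NA` when the unit has no spikes), stat
#'   (test-epoch median divergence), config (the four parameters used).
#' @export
salt_pvalue <- function(spike_times, laser_times, test_window_ms = 10,
                        baseline_span_ms = 1000, n_baseline_epochs = 100,
                        bin_ms = 1) {
  if (length(laser_times) < 50) stop("need >= 50 laser pulses")
  win_s <- test_window_ms / 1000
  span_s <- baseline_span_ms / 1000
  if (n_baseline_epochs * win_s > span_s + 1e-12) {
    stop("baseline span too short for the requested number of epochs")
  }
  if (min(laser_times) < span_s) {
    stop("recording before the first pulse is shorter than the baseline span")
  }
  if (length(laser_times) > 1 &&
      min(diff(laser_times)) < span_s + win_s) {
    stop("pulses too close: baseline epochs would overlap the previous ",
         "pulse's test window")
  }
  cfg <- list(test_window_ms = test_window_ms,
              baseline_span_ms = baseline_span_ms,
              n_baseline_epochs = n_baseline_epochs, bin_ms = bin_ms)
  if (length(spike_times) == 0) {
    return(list(p = NA_real_, stat = NA_real_, config = cfg))
  }
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  offsets <- c(-rev(seq_len(n_baseline_epochs)) * win_s, 0)
  starts <- outer(laser_times, offsets, "+")
  hists <- latency_histograms(spike_times, starts, win_s, bin_ms / 1000)
  scores <- median_js_to_others(hists)
  m <- length(scores)               # baseline epochs are 1..m-1, test is m
  p <- (1 + sum(scores[-m] >= scores[m])) / m
  list(p = p, stat = scores[m], config = cfg)
}

#' Correlation between evoked- and spontaneous-spike waveforms
#'
#' Pearson correlation between the mean waveform of spikes in the 10 ms
#' after laser onset and the mean waveform of all other (spontaneous) spikes.
#'
#' @param unit A `unit_recording` with per-spike waveforms
#'   (`spike_waveforms`, one row per spike).
#' @param laser_times Sorted pulse-onset times (s).
#' @param evoked_window_ms Post-laser window defining evoked spikes.
#' @return List: r (`NA` with reason when either class is empty), n_evoked,
#'   n_spontaneous, reason.
#' @export
evoked_waveform_correlation <- function(unit, laser_times,
                                        evoked_window_ms = 10) {
  if (is.null(unit$spike_waveforms)) {
    stop("unit has no per-spike waveforms")
  }
  s <- unit$spike_times
  w <- evoked_window_ms / 1000
  fi <- findInterval(s, laser_times)
  evoked <- fi >= 1 & (s - laser_times[pmax(fi, 1)]) < w &
    (s - laser_times[pmax(fi, 1)]) >= 0
  if (!any(evoked) || all(evoked)) {
    return(list(r = NA_real_, n_evoked = sum(evoked),
                n_spontaneous = sum(!evoked),
                reason = "empty_spike_class"))
  }
  me <- colMeans(unit$spike_waveforms[evoked, , drop = FALSE])
  ms <- colMeans(unit$spike_waveforms[!evoked, , drop = FALSE])
  list(r = stats::cor(me, ms), n_evoked = sum(evoked),
       n_spontaneous = sum(!evoked), reason = "ok")
}

#' Apply the tagging rule to a table of units
#'
#' Tagged = SALT p < `p_max` AND waveform correlation > `r_min`.
#'
#' @param records Tibble/data.frame with columns `salt_p` and `waveform_r`.
#' @param p_max,r_min Thresholds (defaults 0.01 and 0.9).
#' @return `records` with a logical `tagged` column added.
#' @export
identify_tagged_units <- function(records, p_max = 0.01, r_min = 0.9) {
  records$tagged <- !is.na(records$salt_p) & !is.na(records$waveform_r) &
    records$salt_p < p_max & records$waveform_r > r_min
  records
}

#' Laser-evoked response latency from a fine-binned PSTH
#'
#' Spikes are binned at 0.1-ms resolution in the 10 ms after laser onset.
#' The peak bin of the PSTH is located; for each bin up to and including the
#' peak, the per-pulse rate in that bin is compared (t-test) with the rate
#' averaged over the 10 ms before laser onset. The latency is the left edge
#' of the first bin with P < 0.01.
#'
#' @param spike_times Sorted spike times (s).
#' @param laser_times Sorted pulse-onset times (s).
#' @param bin_ms PSTH bin (default 0.1 ms).
#' @param window_ms Post-laser search window (default 10 ms).
#' @param baseline_ms Pre-laser baseline span (default 10 ms).
#' @param alpha Per-bin significance level (default 0.01).
#' @param alternative Sidedness of the t-test. The default is one-sided
#'   (`"greater"`): the procedure asks when the evoked rate first rises above
#'   baseline, and with 0.1-ms bins a two-sided test fires spuriously on the
#'   tiny rate deficit that sparse baseline spiking produces in early bins.
#' @return List: latency_ms (`NA` with reason when no bin is significant),
#'   peak_ms (left edge of the peak bin), reason.
#' @export
evoked_response_latency <- function(spike_times, laser_times, bin_ms = 0.1,
                                    window_ms = 10, baseline_ms = 10,
                                    alpha = 0.01,
                                    alternative = "greater") {
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  bin_s <- bin_ms / 1000
  win_s <- window_ms / 1000
  n_bins <- as.integer(round(win_s / bin_s))
  np <- length(laser_times)

  lo <- findInterval(laser_times, spike_times, left.open = TRUE)
  hi <- findInterval(laser_times + win_s, spike_times, left.open = TRUE)
  pulse_of <- rep.int(seq_len(np), hi - lo)
  sp <- spike_times[sequence(hi - lo, from = lo + 1L)]
  b <- floor((sp - laser_times[pulse_of]) / bin_s + 1e-9) + 1L
  counts <- matrix(0L, np, n_bins)
  keep <- b >= 1L & b <= n_bins
  if (any(keep)) {
    tab <- table(factor(pulse_of[keep], levels = seq_len(np)),
                 factor(b[keep], levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), np, n_bins)
  }
  base_rate <- n_spikes_in(spike_times, laser_times - baseline_ms / 1000,
                           laser_times) / (baseline_ms / 1000)
  psth <- colMeans(counts) / bin_s
  peak <- which.max(psth)
  for (bb in seq_len(peak)) {
    p <- safe_t_p(counts[, bb] / bin_s - base_rate,
                  alternative = alternative)
    if (!is.na(p) && p < alpha) {
      return(list(latency_ms = (bb - 1) * bin_ms,
                  peak_ms = (peak - 1) * bin_ms, reason = "ok"))
    }
  }
  list(latency_ms = NA_real_, peak_ms = (peak - 1) * bin_ms,
       reason = "no_significant_bin")
}
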