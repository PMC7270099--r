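# Movement-confound controls: does waiting-period spiking merely track
# licking? Three checks: trial-wise spike/lick rate correlation in FA trials,
# lick-triggered spike histograms, and re-analysis on no-lick trials.

#' Spike-rate vs lick-rate correlation in FA trials
#'
#' Uses FA trials with at least one waiting-period lick. Sessions qualify
#' only when that trial count exceeds the area's gate (V1: >20; OFC: >5).
#' Per trial, the spike rate and the lick rate are both computed over the
#' first 0.5 s of the waiting period; Pearson correlation across trials.
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble.
#' @param licks Sorted session-clock lick times.
#' @param area `"V1"` or `"OFC"` (sets the trial-count gate).
#' @param window Rate window relative to stimulus onset (default \[0, 0.5)).
#' @return List of class `lick_control_result`: unit_id, pearson_r, p_value,
#'   n_trials, evaluable (logical), reason.
#' @export
lick_spike_correlation <- function(unit, trials, licks,
                                   area = c("V1", "OFC"),
                                   window = WAITING_WINDOW) {
  area <- match.arg(area)
  gate <- if (area == "V1") 20L else 5L
  if (is.unsorted(licks)) licks <- sort(licks)
  fa <- trials[trials$outcome == "FA", ]
  lick_n <- n_spikes_in(licks, fa$stim_on + window[1], fa$stim_on + window[2])
  fa <- fa[lick_n > 0, ]
  lick_rate <- lick_n[lick_n > 0] / (window[2] - window[1])
  res <- list(unit_id = unit$unit_id, pearson_r = NA_real_,
              p_value = NA_real_, n_trials = nrow(fa),
              evaluable = FALSE, reason = "ok")
  if (nrow(fa) <= gate) {
    res$reason <- "fa_lick_trial_count"
    return(res)
  }
  spike_rate <- event_window_rate(unit$spike_times, fa$stim_on, window)
  if (stats::sd(spike_rate) == 0 || stats::sd(lick_rate) == 0) {
    res$reason <- "zero_variance"
    return(res)
  }
  ct <- stats::cor.test(spike_rate, lick_rate, method = "pearson")
  res$pearson_r <- unname(ct$estimate)
  res$p_value <- ct$p.value
  res$evaluable <- TRUE
  res
}

#' Lick-triggered spike histogram
#'
#' Spike rate in bins around each waiting-period lick, averaged over licks.
#' Licks whose window would extend beyond the waiting period are excluded so
#' that edge bins are not biased by epochs with different rates.
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble (provides waiting-period bounds).
#' @param licks Sorted session-clock lick times.
#' @param half_width_s Half window width around each lick (default 0.25 s).
#' @param bin_s Bin width (default 0.05 s).
#' @return Tibble: t (bin start relative to lick), rate, n_licks; or `NULL`
#'   when no qualifying lick exists.
#' @export
lick_triggered_histogram <- function(unit, trials, licks,
                                     half_width_s = 0.25, bin_s = 0.05) {
  if (is.unsorted(licks)) licks <- sort(licks)
  keep <- logical(length(licks))
  for (i in seq_len(nrow(trials))) {
    in_wait <- licks >= trials$stim_on[i] + half_width_s &
      licks + half_width_s <= trials$waiting_end[i]
    keep <- keep | in_wait
  }
  licks <- licks[keep]
  if (length(licks) == 0) return(NULL)
  edges <- seq(-half_width_s, half_width_s, by = bin_s)
  counts <- numeric(length(edges) - 1L)
  for (l in licks) {
    counts <- counts +
      n_spikes_in(unit$spike_times, l + edges[-length(edges)], l + edges[-1])
  }
  tibble::tibble(t = edges[-length(edges)],
                 rate = counts / (length(licks) * bin_s),
                 n_licks = length(licks))
}

#' Subset of trials without early licks
#'
#' Trials in which no lick occurred within the first `cutoff_s` (default
#' 0.5 s) after stimulus onset, for re-running SI/MI free of early licking.
#'
#' @param trials Trial tibble.
#' @param licks Sorted session-clock lick times.
#' @param cutoff_s Exclusion window after stimulus onset.
#' @return The filtered trial tibble (order preserved; may be empty).
#' @export
no_lick_subset <- function(trials, licks, cutoff_s = 0.5) {
  if (is.unsorted(licks)) licks <- sort(licks)
  n <- n_spikes_in(licks, trials$stim_on, trials$stim_on + cutoff_s)
  trials[n == 0L, ]
}
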