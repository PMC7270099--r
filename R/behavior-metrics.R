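#' Trial-outcome counts and rates
#'
#' Hit rate = N_hits / (N_hits + N_misses); FA rate = N_FAs / (N_FAs + N_CRs);
#' CR rate = N_CRs / (N_FAs + N_CRs). Rates whose denominator is zero are
#' returned as `NA` rather than raising.
#'
#' @param trials Trial tibble with an `outcome` column in
#'   {"hit", "miss", "FA", "CR"}.
#' @return List of class `outcome_rates`: n_hits, n_misses, n_fas, n_crs,
#'   hit_rate, fa_rate, cr_rate.
#' @export
compute_outcome_rates <- function(trials) {
  out <- trials$outcome
  bad <- which(is.na(out) | !out %in% c("hit", "miss", "FA", "CR"))
  if (length(bad) > 0) {
    stop("unlabeled outcome at trial index ",
         paste(utils::head(trials$index[bad], 5), collapse = ", "))
  }
  n_hits <- sum(out == "hit"); n_misses <- sum(out == "miss")
  n_fas <- sum(out == "FA"); n_crs <- sum(out == "CR")
  n_go <- n_hits + n_misses
  n_nogo <- n_fas + n_crs
  structure(
    list(n_hits = n_hits, n_misses = n_misses, n_fas = n_fas, n_crs = n_crs,
         hit_rate = if (n_go > 0) n_hits / n_go else NA_real_,
         fa_rate = if (n_nogo > 0) n_fas / n_nogo else NA_real_,
         cr_rate = if (n_nogo > 0) n_crs / n_nogo else NA_real_),
    class = "outcome_rates")
}

#' Behavioral discriminability (d-prime)
#'
#' d' = qnorm(hit rate) - qnorm(FA rate). Extreme rates (0 or 1) are clipped
#' to 1/(2N) and 1 - 1/(2N) with N the relevant trial count (the standard
#' log-linear correction), so the result is always finite; the counts are
#' only required when clipping is actually needed.
#'
#' @param hit_rate,fa_rate Proportions in \[0, 1\].
#' @param n_go,n_nogo Go and No-Go trial counts (needed for clipping).
#' @return d' (numeric scalar).
#' @export
compute_dprime <- function(hit_rate, fa_rate, n_go = NULL, n_nogo = NULL) {
  clip <- function(r, n, what) {
    if (is.na(r)) return(NA_real_)
    if (r < 0 || r > 1) stop(what, " must be in [0, 1]")
    if (r == 0 || r == 1) {
      if (is.null(n) || n <= 0) {
        stop("trial count required to clip an extreme ", what)
      }
      r <- min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    r
  }
  stats::qnorm(clip(hit_rate, n_go, "hit_rate")) -
    stats::qnorm(clip(fa_rate, n_nogo, "fa_rate"))
}

#' Median first-lick latency of a session
#'
#' Per trial, the first lick within `window_s` (default 1 s) after stimulus
#' onset; the session summary is the median across trials that have such a
#' lick (midpoint convention for even counts). Returns `NA` when no trial
#' qualifies.
#'
#' @param trials Trial tibble with `stim_on`.
#' @param licks Sorted session-clock lick times.
#' @param window_s Latency window after stimulus onset (s).
#' @return Median latency (s) or `NA`.
#' @export
lick_latency_summary <- function(trials, licks, window_s = 1.0) {
  if (is.unsorted(licks)) licks <- sort(licks)
  idx <- findInterval(trials$stim_on, licks, left.open = TRUE) + 1L
  lat <- rep(NA_real_, nrow(trials))
  ok <- idx <= length(licks)
  lat[ok] <- licks[idx[ok]] - trials$stim_on[ok]
  lat[!is.na(lat) & lat >= window_s] <- NA_real_
  if (all(is.na(lat))) return(NA_real_)
  stats::median(lat, na.rm = TRUE)
}

#' Per-session behavioral summary
#'
#' Outcome rates, d', and the median first-lick latency, optionally split by
#' laser condition. With `laser_condition = "all"` rates use all trials
#' (laser-on and laser-off pooled), as done when summarizing sessions with
#' block-interleaved optogenetic stimulation.
#'
#' @param session A `gonogo_session` (or a list with `trials` and `licks`).
#' @param laser_condition One of `"all"`, `"laser_on"`, `"laser_off"`.
#' @return One-row tibble: laser_condition, n_trials, n_hits, n_misses,
#'   n_fas, n_crs, hit_rate, fa_rate, cr_rate, d_prime,
#'   lick_latency_median_s.
#' @export
behavior_summary <- function(session,
                             laser_condition = c("all", "laser_on",
                                                 "laser_off")) {
  laser_condition <- match.arg(laser_condition)
  tr <- session$trials
  tr <- switch(laser_condition,
               all = tr,
               laser_on = tr[tr$laser, ],
               laser_off = tr[!tr$laser, ])
  r <- compute_outcome_rates(tr)
  d <- if (is.na(r$hit_rate) || is.na(r$fa_rate)) NA_real_ else
    compute_dprime(r$hit_rate, r$fa_rate,
                   n_go = r$n_hits + r$n_misses,
                   n_nogo = r$n_fas + r$n_crs)
  tibble::tibble(
    laser_condition = laser_condition, n_trials = nrow(tr),
    n_hits = r$n_hits, n_misses = r$n_misses, n_fas = r$n_fas,
    n_crs = r$n_crs, hit_rate = r$hit_rate, fa_rate = r$fa_rate,
    cr_rate = r$cr_rate, d_prime = d,
    lick_latency_median_s = lick_latency_summary(tr, session$licks))
}
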