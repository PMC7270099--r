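# Fiber-photometry quantification: event-aligned dF/F = (F - F0)/F0 with a
# per-event pre-event baseline F0, peak amplitude/latency of the averaged
# response, and outcome-split waiting-period means for behaving sessions.

#' Event-aligned dF/F traces
#'
#' For each event, F0 is the mean fluorescence over `baseline_window_s`
#' immediately before the event, and dF/F = (F - F0)/F0 is extracted on a
#' common sample-aligned grid spanning the baseline window through
#' `post_s` after the event. Events whose F0 is not positive, or whose span
#' falls outside the trace, are skipped with a message.
#'
#' @param trace A `photometry_trace` (list with `t`, `F`, `fs`).
#' @param events Event times (s, trace clock).
#' @param baseline_window_s Baseline span before each event (s).
#' @param post_s Post-event span (defaults to the smallest inter-event
#'   interval, or the time from the last event to the end of the trace for a
#'   single event).
#' @return List of class `dff_traces`: `t_rel` (s relative to event), `dff`
#'   (events x samples matrix), `F0`, `events`.
#' @export
compute_dff <- function(trace, events, baseline_window_s = 2,
                        post_s = NULL) {
  fs <- trace$fs
  if (is.null(post_s)) {
    post_s <- if (length(events) > 1) min(diff(sort(events))) else
      max(trace$t) - max(events)
  }
  n_pre <- round(baseline_window_s * fs)
  n_post <- round(post_s * fs)
  offs <- seq(-n_pre, n_post)
  t0 <- trace$t[1]
  keep <- logical(length(events))
  rows <- vector("list", length(events))
  f0 <- rep(NA_real_, length(events))
  for (k in seq_along(events)) {
    i_e <- round((events[k] - t0) * fs) + 1L
    idx <- i_e + offs
    if (idx[1] < 1 || idx[length(idx)] > length(trace$F)) {
      message("event ", k, " skipped: span outside trace")
      next
    }
    base <- mean(trace$F[i_e - seq_len(n_pre)])
    if (base <= 0) {
      message("event ", k, " skipped: non-positive baseline F0")
      next
    }
    keep[k] <- TRUE
    f0[k] <- base
    rows[[k]] <- (trace$F[idx] - base) / base
  }
  if (!any(keep)) stop("no usable event")
  structure(
    list(t_rel = offs / fs, dff = do.call(rbind, rows[keep]),
         F0 = f0[keep], events = events[keep]),
    class = "dff_traces")
}

#' Peak dF/F amplitude and latency
#'
#' Averages the per-event dF/F traces and locates the maximum after the event
#' onset.
#'
#' @param dff_traces A `dff_traces` object from [compute_dff()].
#' @return List: peak (dimensionless dF/F), latency_s (time of the peak
#'   relative to the event).
#' @export
peak_response <- function(dff_traces) {
  avg <- colMeans(dff_traces$dff)
  post <- dff_traces$t_rel > 0
  if (!any(post)) stop("no post-event samples")
  i <- which.max(avg[post])
  list(peak = avg[post][i], latency_s = dff_traces$t_rel[post][i])
}

#' Outcome-averaged waiting-period dF/F
#'
#' For behaving-session photometry: per trial, F0 is the mean fluorescence
#' over `baseline_window_s` (default 1 s) before stimulus onset, and the
#' response is the mean dF/F over the waiting period. Trials are grouped by
#' outcome; the CR-vs-FA contrast (CR mean minus FA mean) is reported.
#'
#' @param trace A `photometry_trace` on the session clock.
#' @param trials Trial tibble (`stim_on`, `waiting_end`, `outcome`).
#' @param baseline_window_s Pre-stimulus baseline span (s).
#' @return List: per_trial (tibble index, outcome, dff_mean), cr_mean,
#'   fa_mean (NA when the class is empty), contrast (cr_mean - fa_mean).
#' @export
outcome_averaged_dff <- function(trace, trials, baseline_window_s = 1) {
  fs <- trace$fs
  t0 <- trace$t[1]
  n_base <- round(baseline_window_s * fs)
  vals <- rep(NA_real_, nrow(trials))
  for (k in seq_len(nrow(trials))) {
    i_on <- round((trials$stim_on[k] - t0) * fs) + 1L
    i_end <- round((trials$waiting_end[k] - t0) * fs)
    if (i_on - n_base < 1 || i_end > length(trace$F)) next
    base <- mean(trace$F[i_on - seq_len(n_base)])
    if (base <= 0) next
    vals[k] <- mean((trace$F[i_on:i_end] - base) / base)
  }
  per_trial <- tibble::tibble(index = trials$index,
                              outcome = trials$outcome, dff_mean = vals)
  grp_mean <- function(o) {
    v <- vals[trials$outcome == o & !is.na(vals)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  cr <- grp_mean("CR"); fa <- grp_mean("FA")
  list(per_trial = per_trial, cr_mean = cr, fa_mean = fa,
       contrast = cr - fa)
}
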