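# Waiting-period analysis window. Even when the waiting period lasts 0.7 s,
# anticipatory licking begins near 0.5 s, so all waiting-period indices use
# the first 0.5 s only. Baseline is the 0.2 s before stimulus onset.
WAITING_WINDOW <- c(0, 0.5)
BASELINE_WINDOW <- c(-0.2, 0)

#' Per-trial firing rates in a stimulus-aligned window
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble (needs `stim_on`, `stim`, `outcome`, `laser`).
#' @param window Half-open window \[t0, t1) in s relative to stimulus onset.
#' @return Tibble: index, stim, outcome, laser, rate.
#' @export
trial_rates <- function(unit, trials, window = WAITING_WINDOW) {
  tibble::tibble(
    index = trials$index, stim = trials$stim, outcome = trials$outcome,
    laser = trials$laser,
    rate = event_window_rate(unit$spike_times, trials$stim_on, window))
}

#' Visual-responsiveness inclusion filter
#'
#' V1 rule: mean waiting-period evoked rate > 0.5 spikes/s AND evoked rates
#' significantly higher than the 0.2 s pre-stimulus baseline (one-sided
#' Wilcoxon signed-rank, P < 0.05). OFC rule: evoked significantly different
#' from baseline (two-sided signed-rank, P < 0.05), with no rate floor.
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble.
#' @param area `"V1"` or `"OFC"`.
#' @return List: included (logical), reason (string; "ok" when included),
#'   evoked_mean, baseline_mean, p_value.
#' @export
responsiveness_filter <- function(unit, trials, area = c("V1", "OFC")) {
  area <- match.arg(area)
  if (nrow(trials) < 2) stop("need at least 2 trials")
  ev <- event_window_rate(unit$spike_times, trials$stim_on, WAITING_WINDOW)
  bl <- event_window_rate(unit$spike_times, trials$stim_on, BASELINE_WINDOW)
  res <- list(included = FALSE, reason = "ok",
              evoked_mean = mean(ev), baseline_mean = mean(bl),
              p_value = NA_real_)
  if (all(ev == bl)) {
    res$reason <- "degenerate"
    return(res)
  }
  if (area == "V1") {
    res$p_value <- safe_wilcox_p(ev, bl, paired = TRUE,
                                 alternative = "greater")
    if (mean(ev) <= 0.5) {
      res$reason <- "rate_floor"
    } else if (is.na(res$p_value)) {
      res$reason <- "degenerate"
    } else if (res$p_value >= 0.05) {
      res$reason <- "not_significant"
    } else {
      res$included <- TRUE
    }
  } else {
    res$p_value <- safe_wilcox_p(ev, bl, paired = TRUE,
                                 alternative = "two.sided")
    if (is.na(res$p_value)) {
      res$reason <- "degenerate"
    } else if (res$p_value >= 0.05) {
      res$reason <- "not_significant"
    } else {
      res$included <- TRUE
    }
  }
  res
}

new_index_result <- function(index_name, value, num_mean, den_mean,
                             n_num, n_den, p_value = NA_real_,
                             included = TRUE, reason = "ok") {
  structure(
    list(index_name = index_name, value = value, num_mean = num_mean,
         den_mean = den_mean, n_num = n_num, n_den = n_den,
         p_value = p_value, included = included, reason = reason),
    class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("<%s> value = %s (n = %d/%d, p = %s)%s\n", x$index_name,
              format(x$value, digits = 4), x$n_num, x$n_den,
              format(x$p_value, digits = 3),
              if (x$included) "" else paste0(" [excluded: ", x$reason, "]")))
  invisible(x)
}

ratio_index <- function(a, b) {
  if (is.na(a) || is.na(b) || a + b == 0) return(NA_real_)
  (a - b) / (a + b)
}

#' Selectivity index from condition means
#'
#' SI = (R_Go - R_NoGo) / (R_Go + R_NoGo) on mean waiting-period rates.
#' `NA` when both means are zero.
#'
#' @param r_go,r_nogo Mean rates (>= 0).
#' @return SI in \[-1, 1\] or `NA`.
#' @export
compute_selectivity_index <- function(r_go, r_nogo) {
  if (r_go < 0 || r_nogo < 0) stop("rates must be >= 0")
  ratio_index(r_go, r_nogo)
}

#' Per-unit selectivity index with significance
#'
#' Computes waiting-period rates per trial, averages within Go and No-Go
#' trials, forms SI, and attaches a two-sided rank-sum p across trials.
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble.
#' @param window Analysis window (default first 0.5 s of the waiting period).
#' @return An `index_result`.
#' @export
unit_selectivity_index <- function(unit, trials, window = WAITING_WINDOW) {
  r <- trial_rates(unit, trials, window)
  go <- r$rate[r$stim == "Go"]; ng <- r$rate[r$stim == "No-Go"]
  new_index_result("SI", ratio_index(mean(go), mean(ng)),
                   mean(go), mean(ng), length(go), length(ng),
                   p_value = safe_wilcox_p(go, ng))
}

#' Outcome modulation index (CR vs FA)
#'
#' MI = (R_CR - R_FA) / (R_CR + R_FA) on mean waiting-period rates to the
#' No-Go stimulus. Units from sessions with `min_fa_trials` or fewer FA
#' trials are flagged `included = FALSE` (reason `"fa_count"`); the value is
#' still computed when defined. Per-unit significance is a two-sided Wilcoxon
#' rank-sum test between CR- and FA-trial rates.
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble.
#' @param window Analysis window.
#' @param min_fa_trials Inclusion gate: FA-trial count must exceed this
#'   (default 15).
#' @return An `index_result`.
#' @export
compute_modulation_index <- function(unit, trials, window = WAITING_WINDOW,
                                     min_fa_trials = 15) {
  r <- trial_rates(unit, trials, window)
  cr <- r$rate[r$outcome == "CR"]; fa <- r$rate[r$outcome == "FA"]
  if (length(cr) == 0) {
    return(new_index_result("MI", NA_real_, NA_real_, mean(fa),
                            0L, length(fa), included = FALSE,
                            reason = "no_cr_trials"))
  }
  res <- new_index_result("MI", ratio_index(mean(cr), mean(fa)),
                          mean(cr), mean(fa), length(cr), length(fa),
                          p_value = safe_wilcox_p(cr, fa))
  if (length(fa) <= min_fa_trials) {
    res$included <- FALSE
    res$reason <- "fa_count"
  }
  res
}

#' Response index (evoked vs baseline) per outcome class
#'
#' RI = (R_evoked - R_baseline) / (R_evoked + R_baseline), where R_evoked is
#' the mean waiting-period rate and R_baseline the mean rate in the 0.2 s
#' before stimulus onset, over trials of the requested outcome.
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble.
#' @param outcome One of "hit", "CR", "FA" (or "miss").
#' @param window Evoked window.
#' @param baseline_window Baseline window.
#' @return An `index_result`.
#' @export
compute_response_index <- function(unit, trials, outcome,
                                   window = WAITING_WINDOW,
                                   baseline_window = BASELINE_WINDOW) {
  sel <- trials[trials$outcome == outcome, ]
  if (nrow(sel) == 0) {
    return(new_index_result("RI", NA_real_, NA_real_, NA_real_, 0L, 0L,
                            included = FALSE, reason = "no_trials"))
  }
  ev <- event_window_rate(unit$spike_times, sel$stim_on, window)
  bl <- event_window_rate(unit$spike_times, sel$stim_on, baseline_window)
  new_index_result("RI", ratio_index(mean(ev), mean(bl)),
                   mean(ev), mean(bl), nrow(sel), nrow(sel),
                   p_value = safe_wilcox_p(ev, bl, paired = TRUE))
}

#' Early/late decomposition of SI and MI
#'
#' Recomputes SI and MI on the early (\[0, 0.1) s) and late (\[0.1, 0.5) s)
#' components of the waiting-period response.
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble.
#' @param boundary_s Early/late boundary (default 0.1 s).
#' @param min_fa_trials FA-count gate passed through to the MI.
#' @return List with elements `early` and `late`, each a list of
#'   `index_result`s `si` and `mi`.
#' @export
early_late_indices <- function(unit, trials, boundary_s = 0.1,
                               min_fa_trials = 15) {
  w_early <- c(0, boundary_s)
  w_late <- c(boundary_s, WAITING_WINDOW[2])
  list(
    early = list(
      si = unit_selectivity_index(unit, trials, w_early),
      mi = compute_modulation_index(unit, trials, w_early, min_fa_trials)),
    late = list(
      si = unit_selectivity_index(unit, trials, w_late),
      mi = compute_modulation_index(unit, trials, w_late, min_fa_trials)))
}

#' Rate change between laser conditions
#'
#' @param on,off Mean rates in laser-on and laser-off conditions.
#' @param mode `"relative"`: (on - off) / off (behaving-task convention);
#'   `"symmetric"`: (on - off) / (on + off) (passive-viewing rate change
#'   index).
#' @return Numeric value (`NA` when the denominator is 0).
#' @export
rate_change <- function(on, off, mode = c("relative", "symmetric")) {
  mode <- match.arg(mode)
  if (is.na(on) || is.na(off)) return(NA_real_)
  if (mode == "relative") {
    if (off == 0) return(NA_real_)
    (on - off) / off
  } else {
    ratio_index(on, off)
  }
}

#' Laser-induced rate change for a unit in a behavioral session
#'
#' Compares waiting-period rates between laser-on and laser-off trials of one
#' condition: Go trials, No-Go CR trials, or No-Go FA trials. For the FA
#' condition, units are gated on more than `min_fa_trials` FA trials in each
#' laser condition.
#'
#' @param unit A `unit_recording`.
#' @param trials Trial tibble.
#' @param mode `"relative"` or `"symmetric"` (see [rate_change()]).
#' @param condition `"go"`, `"cr"`, or `"fa"`.
#' @param window Analysis window.
#' @param min_fa_trials FA gate (applies to `condition = "fa"` and `"cr"`
#'   sessions only through the FA counts; default 15).
#' @return An `index_result` (index name `rate_change_rel` or
#'   `rate_change_sym`).
#' @export
laser_rate_change <- function(unit, trials,
                              mode = c("relative", "symmetric"),
                              condition = c("go", "cr", "fa"),
                              window = WAITING_WINDOW, min_fa_trials = 15) {
  mode <- match.arg(mode)
  condition <- match.arg(condition)
  sel <- switch(condition,
                go = trials[trials$stim == "Go", ],
                cr = trials[trials$outcome == "CR", ],
                fa = trials[trials$outcome == "FA", ])
  on_tr <- sel[sel$laser, ]; off_tr <- sel[!sel$laser, ]
  name <- if (mode == "relative") "rate_change_rel" else "rate_change_sym"
  if (nrow(on_tr) == 0 || nrow(off_tr) == 0) {
    return(new_index_result(name, NA_real_, NA_real_, NA_real_,
                            nrow(on_tr), nrow(off_tr), included = FALSE,
                            reason = "missing_laser_condition"))
  }
  on <- event_window_rate(unit$spike_times, on_tr$stim_on, window)
  off <- event_window_rate(unit$spike_times, off_tr$stim_on, window)
  res <- new_index_result(name, rate_change(mean(on), mean(off), mode),
                          mean(on), mean(off), nrow(on_tr), nrow(off_tr),
                          p_value = safe_wilcox_p(on, off))
  if (condition == "fa") {
    n_fa_on <- sum(trials$outcome == "FA" & trials$laser)
    n_fa_off <- sum(trials$outcome == "FA" & !trials$laser)
    if (n_fa_on <= min_fa_trials || n_fa_off <= min_fa_trials) {
      res$included <- FALSE
      res$reason <- "fa_count"
    }
  }
  res
}

unit_psth <- function(unit, event_times, window, bin_s) {
  edges <- seq(window[1], window[2], by = bin_s)
  n_bins <- length(edges) - 1L
  counts <- numeric(n_bins)
  for (e in event_times) {
    counts <- counts +
      n_spikes_in(unit$spike_times, e + edges[-length(edges)], e + edges[-1])
  }
  list(edges = edges, rate = counts / (length(event_times) * bin_s))
}

#' Normalized population PSTH
#'
#' Per unit and condition, a stimulus-aligned PSTH is computed; each unit's
#' PSTHs are divided by the maximum of the peak values across its conditions
#' (so the strongest condition peaks at 1 for every unit) and then averaged
#' across units. Units with no spikes in any condition are dropped with a
#' message.
#'
#' @param units List of `unit_recording`s.
#' @param trials Trial tibble.
#' @param condition_by `"stim"` (Go vs No-Go) or `"outcome"` (hit/FA/CR).
#' @param window Time window relative to stimulus onset.
#' @param bin_s Bin width (default 10 ms).
#' @param smooth_sd_s Gaussian smoothing s.d. in seconds (0 = none), applied
#'   per unit before normalization.
#' @return Tibble: condition, t (bin start), rate (mean normalized rate),
#'   n_units.
#' @export
normalized_population_psth <- function(units, trials,
                                       condition_by = c("stim", "outcome"),
                                       window = c(-0.2, 1.0), bin_s = 0.01,
                                       smooth_sd_s = 0) {
  condition_by <- match.arg(condition_by)
  conds <- if (condition_by == "stim") c("Go", "No-Go") else
    intersect(c("hit", "FA", "CR"), unique(trials$outcome))
  acc <- NULL
  n_used <- 0L
  for (u in units) {
    mats <- lapply(conds, function(cc) {
      sel <- if (condition_by == "stim") trials[trials$stim == cc, ] else
        trials[trials$outcome == cc, ]
      if (nrow(sel) == 0) return(NULL)
      p <- unit_psth(u, sel$stim_on, window, bin_s)$rate
      if (smooth_sd_s > 0) p <- gauss_smooth(p, smooth_sd_s / bin_s)
      p
    })
    peak <- suppressWarnings(max(unlist(mats), na.rm = TRUE))
    if (!is.finite(peak) || peak <= 0) {
      message("dropping unit ", u$unit_id, ": no spikes in any condition")
      next
    }
    norm <- lapply(mats, function(m) if (is.null(m)) NULL else m / peak)
    if (is.null(acc)) {
      acc <- norm
    } else {
      acc <- Map(function(a, b) {
        if (is.null(b)) a else if (is.null(a)) b else a + b
      }, acc, norm)
    }
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no unit with spikes in any condition")
  edges <- seq(window[1], window[2], by = bin_s)
  t0 <- edges[-length(edges)]
  do.call(rbind, Map(function(cc, v) {
    if (is.null(v)) return(NULL)
    tibble::tibble(condition = cc, t = t0, rate = v / n_used,
                   n_units = n_used)
  }, conds, acc))
}
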