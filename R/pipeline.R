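# End-to-end orchestration: simulate a session bundle, run every analysis
# stage, and write one CSV per stage plus a manifest with content hashes so
# a rerun under the same seed can be verified byte for byte.

#' Default pipeline configuration
#'
#' @param n_units Number of simulated units per area.
#' @param sim A [sim_config()] for the behavioral session.
#' @param learning_level Passed to [simulate_behavior()].
#' @param v1_params,ofc_params [unit_params()] generators for V1-like
#'   (CR-suppressed) and projection-OFC-like (CR-enhanced) units.
#' @param n_tagged,n_untagged Units in the tagging stage.
#' @param run_tagging,run_tuning,run_photometry Stage switches.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_units = 8,
                            sim = sim_config(n_trials = 200,
                                             laser_scheme = "nogo_trials"),
                            learning_level = 0.3,
                            v1_params = unit_params(
                              baseline_hz = 6, evoked_gain_go = 1.6,
                              evoked_gain_nogo = 1.2, outcome_gain_cr = 0.7,
                              outcome_gain_fa = 1.1, laser_gain = 1.3),
                            ofc_params = unit_params(
                              baseline_hz = 5, evoked_gain_go = 0.8,
                              evoked_gain_nogo = 1.3, outcome_gain_cr = 1.4,
                              outcome_gain_fa = 0.9),
                            n_tagged = 2, n_untagged = 2,
                            run_tagging = TRUE, run_tuning = TRUE,
                            run_photometry = TRUE) {
  structure(
    list(n_units = n_units, sim = sim, learning_level = learning_level,
         v1_params = v1_params, ofc_params = ofc_params,
         n_tagged = n_tagged, n_untagged = n_untagged,
         run_tagging = run_tagging, run_tuning = run_tuning,
         run_photometry = run_photometry),
    class = "pipeline_config")
}

index_row <- function(unit_id, res) {
  tibble::tibble(unit_id = unit_id, index = res$index_name,
                 value = res$value, num_mean = res$num_mean,
                 den_mean = res$den_mean, n_num = res$n_num,
                 n_den = res$n_den, p_value = res$p_value,
                 included = res$included, reason = res$reason)
}

#' Per-unit index table for a session
#'
#' Runs the inclusion filter, SI, MI, per-outcome RIs, early/late SI/MI,
#' laser rate changes (when both laser conditions exist), and waveform
#' classification for each unit, returning one long-format row per unit and
#' index.
#'
#' @param units List of `unit_recording`s.
#' @param session A `gonogo_session`.
#' @param area `"V1"` or `"OFC"` (inclusion rule).
#' @return Tibble with columns unit_id, index, value, num_mean, den_mean,
#'   n_num, n_den, p_value, included, reason, plus per-unit responsive,
#'   peak_width_ms and cell_type repeated on every row of that unit.
#' @export
analyze_units <- function(units, session, area = "V1") {
  trials <- session$trials
  rows <- lapply(units, function(u) {
    filt <- responsiveness_filter(u, trials, area)
    el <- early_late_indices(u, trials)
    tab <- rbind(
      index_row(u$unit_id, unit_selectivity_index(u, trials)),
      index_row(u$unit_id, compute_modulation_index(u, trials)),
      index_row(u$unit_id, compute_response_index(u, trials, "hit")),
      index_row(u$unit_id, compute_response_index(u, trials, "CR")),
      index_row(u$unit_id, compute_response_index(u, trials, "FA")))
    el_tab <- rbind(index_row(u$unit_id, el$early$si),
                    index_row(u$unit_id, el$early$mi),
                    index_row(u$unit_id, el$late$si),
                    index_row(u$unit_id, el$late$mi))
    el_tab$index <- paste0(el_tab$index,
                           rep(c("_early", "_late"), each = 2))
    tab <- rbind(tab, el_tab)
    if (any(trials$laser) && any(!trials$laser)) {
      tab <- rbind(
        tab,
        index_row(u$unit_id, laser_rate_change(u, trials, "relative", "go")),
        index_row(u$unit_id, laser_rate_change(u, trials, "relative", "cr")),
        index_row(u$unit_id, laser_rate_change(u, trials, "relative", "fa")))
    }
    pw <- peak_half_width(u$waveform)
    tab$responsive <- filt$included
    tab$responsive_reason <- filt$reason
    tab$peak_width_ms <- pw$width_ms
    tab$cell_type <- if (is.na(pw$width_ms)) NA_character_ else
      classify_cell_type(pw$width_ms)
    tab
  })
  do.call(rbind, rows)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Simulates a behavioral session with V1-like and OFC-like units, runs
#' behavior metrics, per-unit indices, lick controls, orientation tuning,
#' phototagging, and photometry stages (as enabled in the config), and writes
#' all outputs plus a hash manifest under `out_dir`. Deterministic: the same
#' config and seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_full_pipeline <- function(config = pipeline_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  session <- simulate_behavior(config$sim, config$learning_level,
                               seed = seed)
  units <- lapply(seq_len(config$n_units), function(i) {
    p <- if (i %% 2 == 1) config$v1_params else config$ofc_params
    simulate_unit(session, p, seed = seed + 1000L + i,
                  unit_id = sprintf("u%02d", i),
                  area = if (i %% 2 == 1) "V1" else "OFC")
  })

  files <- character(0)
  emit <- function(x, name) {
    write_csv_quiet(x, file.path(out_dir, name))
    files <<- c(files, name)
  }

  behavior <- do.call(rbind, lapply(
    c("all", "laser_off", "laser_on"),
    function(lc) behavior_summary(session, lc)))
  emit(behavior, "behavior.csv")

  unit_tab <- analyze_units(units, session,
                            area = units[[1]]$area)
  emit(unit_tab, "units.csv")

  controls <- do.call(rbind, lapply(units, function(u) {
    r <- lick_spike_correlation(u, session$trials, session$licks,
                                area = u$area)
    tibble::tibble(unit_id = u$unit_id, pearson_r = r$pearson_r,
                   p_value = r$p_value, n_trials = r$n_trials,
                   evaluable = r$evaluable, reason = r$reason)
  }))
  emit(controls, "controls.csv")

  results <- list(session = session, behavior = behavior,
                  units = unit_tab, controls = controls)

  if (config$run_tuning) {
    rec <- simulate_tuning_session(seed = seed + 2000L, laser_gain = 0.7)
    curve <- build_tuning_curve(rec, laser = FALSE)
    inc <- tuning_inclusion(curve)
    tuning <- tibble::tibble(
      direction_deg = curve$directions, mean_rate = curve$mean_rate,
      osi = inc$osi, t_stat = inc$t_stat, peak_rate = inc$peak_rate,
      included = inc$included,
      rate_change_index = tuning_laser_rate_change(rec))
    emit(tuning, "tuning.csv")
    results$tuning <- tuning
  }

  if (config$run_tagging) {
    n_tag_units <- config$n_tagged + config$n_untagged
    tagging <- do.call(rbind, lapply(seq_len(n_tag_units), function(i) {
      p <- unit_params(baseline_hz = 5, tagged = i <= config$n_tagged)
      tb <- simulate_tagging_block(p, seed = seed + 3000L + i,
                                   unit_id = sprintf("t%02d", i))
      salt <- salt_pvalue(tb$unit$spike_times, tb$laser_times)
      wf <- evoked_waveform_correlation(tb$unit, tb$laser_times)
      lat <- evoked_response_latency(tb$unit$spike_times, tb$laser_times)
      tibble::tibble(unit_id = tb$unit$unit_id, salt_p = salt$p,
                     waveform_r = wf$r, latency_ms = lat$latency_ms,
                     n_pulses = length(tb$laser_times))
    }))
    tagging <- identify_tagged_units(tagging)
    emit(tagging, "tagging.csv")
    results$tagging <- tagging
  }

  if (config$run_photometry) {
    ev <- seq(10, 100, by = 10)
    trace <- simulate_photometry(ev, kernel_amplitude = 0.4,
                                 kernel_tau_s = 1, baseline_F = 2,
                                 noise_sd = 0.02, duration_s = max(ev) + 10,
                                 seed = seed + 4000L)
    d <- compute_dff(trace, ev, baseline_window_s = 2, post_s = 8)
    pk <- peak_response(d)
    emit(tibble::tibble(peak_dff = pk$peak, latency_s = pk$latency_s,
                        n_events = length(d$events)),
         "photometry_summary.csv")
    results$photometry <- pk
  }

  manifest <- list(
    schema_version = SCHEMA_VERSION, seed = seed,
    stages = files,
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
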