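# Session-bundle interchange. A bundle directory holds plain CSV files
# (trials.csv, licks.csv, spikes.csv, waveforms.csv, laser_pulses.csv,
# photometry.csv) plus a JSON manifest with the schema version, config,
# seed, and content hashes of every file written.

SCHEMA_VERSION <- "1.0"

write_csv_quiet <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
}

read_csv_quiet <- function(path, ...) {
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...),
    warning = function(w) {
      stop("malformed CSV in ", basename(path), ": ", conditionMessage(w))
    })
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    stop("malformed CSV in ", basename(path), " at line ", prob$row[1],
         ": ", prob$expected[1])
  }
  out
}

#' Write a session bundle to a directory
#'
#' @param dir Output directory (created if needed).
#' @param session A `gonogo_session`.
#' @param units Optional list of `unit_recording`s.
#' @param laser_pulses Optional numeric vector of tagging-pulse times.
#' @param photometry Optional `photometry_trace`.
#' @param seed Seed recorded in the manifest.
#' @return The manifest (invisibly).
#' @export
write_session_bundle <- function(dir, session, units = list(),
                                 laser_pulses = NULL, photometry = NULL,
                                 seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(x, name) {
    path <- file.path(dir, name)
    write_csv_quiet(x, path)
    files <<- c(files, name)
  }
  put(session$trials, "trials.csv")
  put(tibble::tibble(time = session$licks), "licks.csv")
  if (length(units) > 0) {
    put(do.call(rbind, lapply(units, function(u) {
      tibble::tibble(unit_id = u$unit_id, time = u$spike_times,
                     area = u$area)
    })), "spikes.csv")
    put(do.call(rbind, lapply(units, function(u) {
      tibble::tibble(unit_id = u$unit_id,
                     sample_index = seq_along(u$waveform$samples),
                     amplitude = u$waveform$samples,
                     dt_ms = u$waveform$dt_ms)
    })), "waveforms.csv")
  }
  if (!is.null(laser_pulses)) {
    put(tibble::tibble(time = laser_pulses), "laser_pulses.csv")
  }
  if (!is.null(photometry)) {
    put(tibble::tibble(t = photometry$t, F = photometry$F), "photometry.csv")
  }
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    seed = seed,
    session_index = session$session_index,
    n_trials = nrow(session$trials),
    config = session$config[setdiff(names(session$config), "seed")],
    files = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a session bundle
#'
#' @param dir Bundle directory written by [write_session_bundle()].
#' @return List: session (`gonogo_session`), units (list of
#'   `unit_recording`s), laser_pulses, photometry, manifest.
#' @export
read_session_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, SCHEMA_VERSION)) {
    stop("schema version mismatch: bundle is ", manifest$schema_version,
         ", reader supports ", SCHEMA_VERSION, "; migrate the bundle")
  }
  trials <- read_csv_quiet(file.path(dir, "trials.csv"),
                           col_types = "icldddcd")
  licks <- read_csv_quiet(file.path(dir, "licks.csv"))$time
  cfg <- manifest$config
  config <- sim_config(
    n_trials = cfg$n_trials, p_go = cfg$p_go, waiting_s = cfg$waiting_s,
    answer_s = cfg$answer_s, iti_s = cfg$iti_s, timeout_s = cfg$timeout_s,
    reward_ul = cfg$reward_ul, p_lick_go = cfg$p_lick_go,
    p_lick_nogo = cfg$p_lick_nogo, lick_rate_hz = cfg$lick_rate_hz,
    lick_onset_s = cfg$lick_onset_s,
    answer_lick_rate_hz = cfg$answer_lick_rate_hz,
    laser_block_len = cfg$laser_block_len, laser_scheme = cfg$laser_scheme,
    seed = manifest$seed)
  session <- structure(
    list(trials = trials, licks = if (is.null(licks)) numeric(0) else licks,
         config = config,
         session_index = as.integer(manifest$session_index)),
    class = "gonogo_session")

  units <- list()
  if (file.exists(file.path(dir, "spikes.csv"))) {
    sp <- read_csv_quiet(file.path(dir, "spikes.csv"))
    wf <- read_csv_quiet(file.path(dir, "waveforms.csv"))
    for (uid in unique(sp$unit_id)) {
      wsub <- wf[wf$unit_id == uid, ]
      tpl <- structure(
        list(samples = wsub$amplitude[order(wsub$sample_index)],
             dt_ms = wsub$dt_ms[1],
             t_ms = (wsub$sample_index[order(wsub$sample_index)] - 1) *
               wsub$dt_ms[1]),
        class = "waveform_template")
      units[[uid]] <- new_unit_recording(
        sp$time[sp$unit_id == uid], tpl, unit_id = uid,
        area = sp$area[sp$unit_id == uid][1])
    }
  }
  laser_pulses <- NULL
  if (file.exists(file.path(dir, "laser_pulses.csv"))) {
    laser_pulses <- read_csv_quiet(file.path(dir, "laser_pulses.csv"))$time
  }
  photometry <- NULL
  if (file.exists(file.path(dir, "photometry.csv"))) {
    ph <- read_csv_quiet(file.path(dir, "photometry.csv"))
    fs <- 1 / stats::median(diff(ph$t))
    photometry <- structure(
      list(t = ph$t, F = ph$F, events = numeric(0), fs = round(fs)),
      class = "photometry_trace")
  }
  list(session = session, units = units, laser_pulses = laser_pulses,
       photometry = photometry, manifest = manifest)
}
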