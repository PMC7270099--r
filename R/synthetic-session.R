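#' Configuration for a simulated Go/No-Go session
#'
#' Bundles the task-structure constants and lick-behavior probabilities used
#' by [simulate_behavior()]. Defaults reflect the standard protocol: 50/50
#' random Go/No-Go interleaving, a 0.7 s waiting period in which the grating
#' is static and licking has no consequence, a 2.2 s answer period in which
#' licking on a Go trial is rewarded (5.5 ul of water), a 4 s timeout for ITI
#' licking, and optogenetic laser stimulation organized in alternating blocks
#' of 20 trials.
#'
#' @param n_trials Number of trials.
#' @param p_go Probability that a trial is a Go trial.
#' @param waiting_s,answer_s,iti_s,timeout_s Epoch durations (s).
#' @param reward_ul Reward volume (ul); metadata only.
#' @param p_lick_go Probability of an answer-period lick on a Go trial
#'   (hit probability).
#' @param p_lick_nogo Probability of an answer-period lick on a No-Go trial
#'   (false-alarm probability) before any learning adjustment.
#' @param lick_rate_hz Rate of anticipatory waiting-period licking on hit and
#'   FA trials (homogeneous Poisson after `lick_onset_s`).
#' @param lick_onset_s Earliest anticipatory lick time after stimulus onset.
#'   With the default 0.3 s and `lick_rate_hz = 4` the median first-lick
#'   latency is near 0.45-0.5 s, as observed in trained mice.
#' @param answer_lick_rate_hz Lick rate during the answer period on hit/FA
#'   trials (at least one answer-period lick is guaranteed).
#' @param laser_block_len Trials per laser block (alternating off/on blocks).
#' @param laser_scheme One of `"none"`, `"nogo_trials"`, `"go_trials"`:
#'   which stimulus class receives laser stimulation inside laser-on blocks.
#' @param seed Optional RNG seed recorded in the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 300, p_go = 0.5,
                       waiting_s = 0.7, answer_s = 2.2,
                       iti_s = 3, timeout_s = 4, reward_ul = 5.5,
                       p_lick_go = 0.95, p_lick_nogo = 0.5,
                       lick_rate_hz = 4, lick_onset_s = 0.3,
                       answer_lick_rate_hz = 6,
                       laser_block_len = 20,
                       laser_scheme = c("none", "nogo_trials", "go_trials"),
                       seed = NULL) {
  laser_scheme <- match.arg(laser_scheme)
  assert_prob(p_go, "p_go")
  assert_prob(p_lick_go, "p_lick_go")
  assert_prob(p_lick_nogo, "p_lick_nogo")
  assert_pos(waiting_s, "waiting_s")
  assert_pos(answer_s, "answer_s")
  assert_pos(iti_s, "iti_s")
  assert_pos(timeout_s, "timeout_s")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (laser_block_len < 1) stop("laser_block_len must be >= 1")
  if (lick_rate_hz < 0 || answer_lick_rate_hz <= 0) {
    stop("lick rates must be non-negative (answer rate positive)")
  }
  structure(
    list(n_trials = as.integer(n_trials), p_go = p_go,
         waiting_s = waiting_s, answer_s = answer_s, iti_s = iti_s,
         timeout_s = timeout_s, reward_ul = reward_ul,
         p_lick_go = p_lick_go, p_lick_nogo = p_lick_nogo,
         lick_rate_hz = lick_rate_hz, lick_onset_s = lick_onset_s,
         answer_lick_rate_hz = answer_lick_rate_hz,
         laser_block_len = as.integer(laser_block_len),
         laser_scheme = laser_scheme, seed = seed),
    class = "sim_config")
}

# Poisson event times on [a, b) at constant rate (sorted).
rpois_times <- function(rate, a, b) {
  if (rate <= 0 || b <= a) return(numeric(0))
  n <- stats::rpois(1, rate * (b - a))
  sort(stats::runif(n, a, b))
}

#' Simulate one Go/No-Go behavioral session
#'
#' Draws a random Go/No-Go trial sequence, Bernoulli answer-period licking
#' (hit/FA vs miss/CR), anticipatory waiting-period licks on hit/FA trials,
#' and a block-interleaved laser schedule. `learning_level` scales the
#' false-alarm probability down linearly
#' (`p_fa = p_lick_nogo * (1 - learning_level)`), emulating the rise of the
#' correct-rejection rate with training while the hit rate stays high.
#'
#' @param config A [sim_config()].
#' @param learning_level Fraction in \[0, 1\]; 0 = naive, 1 = perfect CR.
#' @param seed RNG seed (integer). Required for reproducibility.
#' @param session_index Ordinal position in a training sequence (metadata).
#' @return A list of class `gonogo_session` with elements `trials` (tibble:
#'   index, stim, laser, stim_on, waiting_end, answer_end, outcome,
#'   first_lick), `licks` (sorted session-clock lick times), `config`,
#'   `session_index`.
#' @export
simulate_behavior <- function(config, learning_level = 0, seed = NULL,
                              session_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(learning_level) || learning_level < 0 || learning_level > 1) {
    stop("learning_level must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  p_fa <- config$p_lick_nogo * (1 - learning_level)

  stim <- ifelse(stats::runif(n) < config$p_go, "Go", "No-Go")
  trial_len <- config$waiting_s + config$answer_s
  stim_on <- config$iti_s + (seq_len(n) - 1L) * (trial_len + config$iti_s)
  waiting_end <- stim_on + config$waiting_s
  answer_end <- waiting_end + config$answer_s

  block <- ((seq_len(n) - 1L) %/% config$laser_block_len) %% 2L == 1L
  laser <- switch(config$laser_scheme,
    none = rep(FALSE, n),
    nogo_trials = block & stim == "No-Go",
    go_trials = block & stim == "Go")

  licked <- ifelse(stim == "Go",
                   stats::runif(n) < config$p_lick_go,
                   stats::runif(n) < p_fa)
  outcome <- ifelse(stim == "Go",
                    ifelse(licked, "hit", "miss"),
                    ifelse(licked, "FA", "CR"))

  licks <- vector("list", n)
  first_lick <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!licked[i]) next
    ant <- rpois_times(config$lick_rate_hz,
                       config$lick_onset_s, config$waiting_s)
    # First answer-period lick from a truncated exponential so hit/FA trials
    # always contain one; further licks Poisson until the answer period ends.
    r <- config$answer_lick_rate_hz
    u <- stats::runif(1)
    t1 <- -log(1 - u * (1 - exp(-r * config$answer_s))) / r
    ans <- c(config$waiting_s + t1,
             rpois_times(r, config$waiting_s + t1, trial_len))
    rel <- sort(c(ant, ans))
    licks[[i]] <- stim_on[i] + rel
    first_lick[i] <- rel[1]
  }

  trials <- tibble::tibble(
    index = seq_len(n), stim = stim, laser = laser,
    stim_on = stim_on, waiting_end = waiting_end, answer_end = answer_end,
    outcome = outcome, first_lick = first_lick)

  structure(
    list(trials = trials, licks = sort(unlist(licks)), config = config,
         session_index = as.integer(session_index)),
    class = "gonogo_session")
}

#' Generative parameters of a simulated unit
#'
#' Rate model: an inhomogeneous Poisson process with piecewise-constant rate.
#' Outside the stimulus the rate is `baseline_hz`. During the waiting period
#' the rate is `baseline_hz` times the stimulus gain (`evoked_gain_go` or
#' `evoked_gain_nogo`); after `early_late_boundary_s` the outcome gain
#' (`outcome_gain_cr` in CR trials, `outcome_gain_fa` in FA trials) also
#' multiplies in. On laser trials `laser_gain` multiplies throughout the
#' stimulus. Gains are multiplicative so that ratio indices computed from
#' condition means recover `(g - 1)/(g + 1)` in expectation.
#'
#' @param baseline_hz Baseline firing rate (spikes/s).
#' @param evoked_gain_go,evoked_gain_nogo Waiting-period stimulus gains.
#' @param outcome_gain_cr,outcome_gain_fa Late-component outcome gains
#'   (applied in CR / FA trials only).
#' @param laser_gain Multiplicative laser effect during stimulus on laser
#'   trials.
#' @param early_late_boundary_s Boundary between the early and late waiting
#'   components (s); outcome gains act only after it.
#' @param waveform_kind `"broad"` or `"narrow"` mean-waveform template.
#' @param tagged Whether the unit emits short-latency laser-evoked spikes.
#' @param tag_latency_s,tag_jitter_s Mean and s.d. of the evoked-spike
#'   latency (s).
#' @param tag_reliability Per-pulse probability of an evoked spike.
#' @param waveform_noise_sd Per-spike waveform noise s.d. (template units)
#'   used when per-spike waveforms are generated.
#' @return A list of class `unit_params`.
#' @export
unit_params <- function(baseline_hz = 5,
                        evoked_gain_go = 1, evoked_gain_nogo = 1,
                        outcome_gain_cr = 1, outcome_gain_fa = 1,
                        laser_gain = 1, early_late_boundary_s = 0.1,
                        waveform_kind = c("broad", "narrow"),
                        tagged = FALSE, tag_latency_s = 0.003,
                        tag_jitter_s = 3e-4, tag_reliability = 0.8,
                        waveform_noise_sd = 0.02) {
  waveform_kind <- match.arg(waveform_kind)
  gains <- c(evoked_gain_go, evoked_gain_nogo, outcome_gain_cr,
             outcome_gain_fa, laser_gain)
  if (baseline_hz < 0) stop("baseline_hz must be >= 0")
  if (any(!is.finite(gains)) || any(gains < 0)) stop("gains must be >= 0")
  if (tag_latency_s < 0) stop("tag_latency_s must be >= 0")
  assert_prob(tag_reliability, "tag_reliability")
  structure(
    list(baseline_hz = baseline_hz,
         evoked_gain_go = evoked_gain_go, evoked_gain_nogo = evoked_gain_nogo,
         outcome_gain_cr = outcome_gain_cr, outcome_gain_fa = outcome_gain_fa,
         laser_gain = laser_gain,
         early_late_boundary_s = early_late_boundary_s,
         waveform_kind = waveform_kind, tagged = tagged,
         tag_latency_s = tag_latency_s, tag_jitter_s = tag_jitter_s,
         tag_reliability = tag_reliability,
         waveform_noise_sd = waveform_noise_sd),
    class = "unit_params")
}

new_unit_recording <- function(spike_times, waveform, unit_id = "u1",
                               area = "V1", spike_waveforms = NULL) {
  structure(
    list(unit_id = unit_id, spike_times = spike_times, waveform = waveform,
         area = area, spike_waveforms = spike_waveforms),
    class = "unit_recording")
}

#' Simulate a unit's spike train for a behavioral session
#'
#' Realizes the piecewise-constant inhomogeneous Poisson model described in
#' [unit_params()]: per segment, the spike count is Poisson with mean rate x
#' duration and spike times are uniform within the segment.
#'
#' @param session A [simulate_behavior()] session.
#' @param params A [unit_params()].
#' @param seed RNG seed.
#' @param unit_id,area Metadata for the returned recording.
#' @return A `unit_recording`: sorted `spike_times` (s, session clock),
#'   mean `waveform` (template), `unit_id`, `area`.
#' @export
simulate_unit <- function(session, params, seed = NULL,
                          unit_id = "u1", area = "V1") {
  stopifnot(inherits(session, "gonogo_session"),
            inherits(params, "unit_params"))
  tr <- session$trials
  if (nrow(tr) == 0) stop("session has no trials")
  if (!is.null(seed)) set.seed(seed)

  b <- params$early_late_boundary_s
  stim_gain <- ifelse(tr$stim == "Go",
                      params$evoked_gain_go, params$evoked_gain_nogo)
  out_gain <- ifelse(tr$outcome == "CR", params$outcome_gain_cr,
                     ifelse(tr$outcome == "FA", params$outcome_gain_fa, 1))
  las_gain <- ifelse(tr$laser, params$laser_gain, 1)

  # Segments: pre-trial gap at baseline, early waiting, late waiting, answer.
  gap_start <- c(0, tr$answer_end[-nrow(tr)])
  seg_start <- c(gap_start, tr$stim_on, tr$stim_on + b, tr$waiting_end)
  seg_end <- c(tr$stim_on, tr$stim_on + b, tr$waiting_end, tr$answer_end)
  base <- params$baseline_hz
  seg_rate <- c(rep(base, nrow(tr)),
                base * stim_gain * las_gain,
                base * stim_gain * out_gain * las_gain,
                base * stim_gain * las_gain)
  if (any(seg_rate < 0)) stop("negative rate; check gains")

  counts <- stats::rpois(length(seg_rate), seg_rate * (seg_end - seg_start))
  tot <- sum(counts)
  spikes <- sort(rep(seg_start, counts) +
                   stats::runif(tot) * rep(seg_end - seg_start, counts))
  new_unit_recording(spikes, waveform_template(params$waveform_kind),
                     unit_id = unit_id, area = area)
}

#' Simulate an optogenetic tagging block
#'
#' Laser pulses are delivered periodically; a tagged unit adds one spike per
#' pulse with probability `tag_reliability` at latency
#' `Normal(tag_latency_s, tag_jitter_s)`, on top of homogeneous Poisson
#' background spiking at `baseline_hz`. Per-spike waveforms (template +
#' Gaussian noise) are attached so that evoked/spontaneous waveform
#' correlations can be computed.
#'
#' @param params A [unit_params()].
#' @param n_pulses Number of laser pulses (default 400).
#' @param pulse_period_s Pulse period (default 2 s, i.e. 0.5 Hz).
#' @param pulse_width_s Pulse width (metadata; default 5 ms).
#' @param seed RNG seed.
#' @param pre_s Recording time before the first pulse (must cover the SALT
#'   baseline span).
#' @param unit_id,area Metadata.
#' @return List with `laser_times` and `unit` (a `unit_recording` with
#'   per-spike waveforms).
#' @export
simulate_tagging_block <- function(params, n_pulses = 400,
                                   pulse_period_s = 2, pulse_width_s = 0.005,
                                   seed = NULL, pre_s = 2,
                                   unit_id = "u1", area = "OFC") {
  stopifnot(inherits(params, "unit_params"))
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (params$tag_latency_s < 0) stop("tag_latency_s must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  laser_times <- pre_s + (seq_len(n_pulses) - 1) * pulse_period_s
  span <- pre_s + n_pulses * pulse_period_s
  spikes <- rpois_times(params$baseline_hz, 0, span)
  if (isTRUE(params$tagged)) {
    hit <- stats::runif(n_pulses) < params$tag_reliability
    lat <- stats::rnorm(sum(hit), params$tag_latency_s, params$tag_jitter_s)
    spikes <- sort(c(spikes, laser_times[hit] + pmax(lat, 0)))
  }
  tpl <- waveform_template(params$waveform_kind)
  wf <- NULL
  if (length(spikes) > 0) {
    wf <- matrix(rep(tpl$samples, each = length(spikes)),
                 nrow = length(spikes))
    if (params$waveform_noise_sd > 0) {
      wf <- wf + stats::rnorm(length(wf), sd = params$waveform_noise_sd)
    }
  }
  list(laser_times = laser_times,
       unit = new_unit_recording(spikes, tpl, unit_id = unit_id, area = area,
                                 spike_waveforms = wf))
}

#' Simulate a passive orientation-tuning experiment
#'
#' Drifting gratings at `n_directions` directions (default 12, spaced 30
#' degrees), each repeated `n_repeats` times per laser condition (default 14),
#' in randomized order. Per-trial drifting-period rates follow an
#' orientation-tuned (period 180 degrees) von Mises profile
#' `baseline_hz + peak_hz * exp(kappa * (cos(2 * (theta - pref)) - 1))`,
#' multiplied by `laser_gain` on laser trials; counts are Poisson over the
#' 2 s drifting epoch.
#'
#' @param n_directions,n_repeats Stimulus grid.
#' @param pref_direction Preferred direction (degrees).
#' @param kappa Tuning concentration (>= 0; 0 = untuned).
#' @param peak_hz Tuned rate at the preferred direction above baseline.
#' @param baseline_hz Untuned rate floor.
#' @param laser_gain Multiplicative laser effect.
#' @param drift_s Drifting-epoch duration used to convert counts to rates.
#' @param seed RNG seed.
#' @return A tibble of class `tuning_recording`: direction_deg, rep, laser,
#'   count, rate_hz, with attribute `drift_s`.
#' @export
simulate_tuning_session <- function(n_directions = 12, n_repeats = 14,
                                    pref_direction = 90, kappa = 2,
                                    peak_hz = 10, baseline_hz = 0.5,
                                    laser_gain = 1, drift_s = 2,
                                    seed = NULL) {
  if (n_directions < 2) stop("n_directions must be >= 2")
  if (kappa < 0) stop("kappa must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dirs <- seq(0, 360, length.out = n_directions + 1)[seq_len(n_directions)]
  grid <- expand.grid(direction_deg = dirs, rep = seq_len(n_repeats),
                      laser = c(FALSE, TRUE))
  grid <- grid[sample.int(nrow(grid)), ]
  th <- grid$direction_deg * pi / 180
  pref <- pref_direction * pi / 180
  rate <- baseline_hz + peak_hz * exp(kappa * (cos(2 * (th - pref)) - 1))
  rate <- rate * ifelse(grid$laser, laser_gain, 1)
  count <- stats::rpois(nrow(grid), rate * drift_s)
  out <- tibble::tibble(direction_deg = grid$direction_deg, rep = grid$rep,
                        laser = grid$laser, count = count,
                        rate_hz = count / drift_s)
  attr(out, "drift_s") <- drift_s
  class(out) <- c("tuning_recording", class(out))
  out
}

#' Simulate a fiber-photometry trace
#'
#' Fluorescence is a constant baseline plus an event-locked, peak-normalized
#' double-exponential kernel (GCaMP-like rise and decay) of amplitude
#' `kernel_amplitude`, plus white noise. Because the kernel peak is exactly
#' 1, a noise-free event yields peak dF/F = `kernel_amplitude / baseline_F`.
#'
#' @param events Event times (s); must lie within the trace span.
#' @param kernel_amplitude Kernel amplitude (fluorescence units).
#' @param kernel_tau_s Decay time constant (s); rise constant is
#'   `kernel_tau_s / 10`.
#' @param baseline_F Baseline fluorescence (> 0).
#' @param noise_sd White-noise s.d.
#' @param fs Sampling rate (Hz; 200 in typical acquisitions).
#' @param duration_s Trace length; defaults to max(events) + 5 * tau.
#' @param seed RNG seed.
#' @return A list of class `photometry_trace`: `t`, `F`, `events`, `fs`.
#' @export
simulate_photometry <- function(events, kernel_amplitude, kernel_tau_s = 1,
                                baseline_F = 1, noise_sd = 0, fs = 200,
                                duration_s = NULL, seed = NULL) {
  if (fs <= 0) stop("fs must be > 0")
  if (baseline_F <= 0) stop("baseline_F must be > 0")
  if (is.null(duration_s)) duration_s <- max(events) + 5 * kernel_tau_s
  if (any(events < 0 | events > duration_s)) {
    stop("events must lie within the trace span")
  }
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = 1 / fs)
  tau_r <- kernel_tau_s / 10
  f <- rep(baseline_F, length(t))
  for (e in events) {
    dt <- t - e
    on <- dt >= 0
    # Normalized on the sampling grid so the realized peak is exactly 1.
    k <- exp(-dt[on] / kernel_tau_s) - exp(-dt[on] / tau_r)
    f[on] <- f[on] + kernel_amplitude * k / max(k)
  }
  if (noise_sd > 0) f <- f + stats::rnorm(length(t), sd = noise_sd)
  structure(list(t = t, F = f, events = sort(events), fs = fs),
            class = "photometry_trace")
}
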