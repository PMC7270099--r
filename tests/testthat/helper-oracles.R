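# Independent oracles used to freeze expected values.

# Naive per-spike loop counterpart of event_window_rate.
naive_window_rate <- function(spikes, events, window) {
  vapply(events, function(e) {
    sum(spikes >= e + window[1] & spikes < e + window[2]) /
      (window[2] - window[1])
  }, 0)
}

# OSI as the modulus of the doubled-angle complex resultant.
osi_complex_oracle <- function(rates, directions_deg) {
  a <- directions_deg * pi / 180
  Mod(sum(rates * exp(2i * a))) / sum(rates)
}

# Minimal hand-built trial table.
make_trials <- function(outcomes, stim = NULL, laser = FALSE,
                        waiting_s = 0.7, answer_s = 2.2, gap_s = 3) {
  n <- length(outcomes)
  if (is.null(stim)) {
    stim <- ifelse(outcomes %in% c("hit", "miss"), "Go", "No-Go")
  }
  stim_on <- gap_s + (seq_len(n) - 1) * (waiting_s + answer_s + gap_s)
  tibble::tibble(index = seq_len(n), stim = stim,
                 laser = rep_len(laser, n), stim_on = stim_on,
                 waiting_end = stim_on + waiting_s,
                 answer_end = stim_on + waiting_s + answer_s,
                 outcome = outcomes, first_lick = NA_real_)
}

# Unit with explicitly placed spikes and a standard waveform.
make_unit <- function(spike_times, unit_id = "u1", area = "V1",
                      kind = "broad") {
  structure(
    list(unit_id = unit_id, spike_times = sort(spike_times),
         waveform = waveform_template(kind), area = area,
         spike_waveforms = NULL),
    class = "unit_recording")
}
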