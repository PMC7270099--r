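test_that("identical latency structure in every epoch is never significant", {
  # one spike at the same offset inside every 10-ms epoch of every pulse
  pulses <- 2 + (0:99) * 2
  offsets <- c(-rev(seq_len(100)) * 0.01, 0)
  spikes <- sort(as.vector(outer(pulses, offsets + 0.003, "+")))
  res <- salt_pvalue(spikes, pulses)
  expect_gt(res$p, 0.5)
})

test_that("SALT p is invariant to a global time shift", {
  p <- unit_params(baseline_hz = 10, tagged = TRUE)
  tb <- simulate_tagging_block(p, n_pulses = 100, seed = 79)
  a <- salt_pvalue(tb$unit$spike_times, tb$laser_times)
  b <- salt_pvalue(tb$unit$spike_times + 123.4, tb$laser_times + 123.4)
  expect_equal(a$p, b$p)
  expect_equal(a$stat, b$stat)
})

test_that("SALT null p-values are close to uniform at desk scale", {
  ps <- vapply(1:150, function(i) {
    tb <- simulate_tagging_block(unit_params(baseline_hz = 8), n_pulses = 200,
                                 seed = 790 + i)
    salt_pvalue(tb$unit$spike_times, tb$laser_times)$p
  }, 0)
  n05 <- sum(ps < 0.05)
  expect_gte(n05, qbinom(0.005, 150, 0.05))
  expect_lte(n05, qbinom(0.995, 150, 0.05))
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("tagged units are detected with small SALT p-values", {
  ps <- vapply(1:15, function(i) {
    tb <- simulate_tagging_block(
      unit_params(baseline_hz = 8, tagged = TRUE), seed = 890 + i)
    salt_pvalue(tb$unit$spike_times, tb$laser_times)$p
  }, 0)
  expect_true(all(ps < 0.01))
})

test_that("SALT rejects undersized inputs and handles empty spike trains", {
  pulses <- 2 + (0:59) * 2
  expect_error(salt_pvalue(c(1, 2, 3), pulses[1:10]), ">= 50")
  expect_error(salt_pvalue(c(1, 2, 3), pulses, baseline_span_ms = 500),
               "baseline span too short")
  expect_error(salt_pvalue(c(1, 2), pulses + 10,
                           test_window_ms = 10, baseline_span_ms = 2500,
                           n_baseline_epochs = 250),
               "too close|shorter")
  expect_true(is.na(salt_pvalue(numeric(0), pulses)$p))
})

test_that("waveform correlation separates matching from inverted shapes", {
  p <- unit_params(baseline_hz = 10, tagged = TRUE, waveform_noise_sd = 0)
  tb <- simulate_tagging_block(p, n_pulses = 100, seed = 99)
  r <- evoked_waveform_correlation(tb$unit, tb$laser_times)
  expect_equal(r$r, 1)

  inv <- tb$unit
  evoked_idx <- rep(FALSE, length(inv$spike_times))
  fi <- findInterval(inv$spike_times, tb$laser_times)
  d <- inv$spike_times - tb$laser_times[pmax(fi, 1)]
  evoked_idx <- fi >= 1 & d >= 0 & d < 0.01
  inv$spike_waveforms[evoked_idx, ] <- -inv$spike_waveforms[evoked_idx, ]
  ri <- evoked_waveform_correlation(inv, tb$laser_times)
  expect_equal(ri$r, -1)

  # same template plus noise keeps r high
  rs <- vapply(1:10, function(i) {
    tbn <- simulate_tagging_block(
      unit_params(baseline_hz = 10, tagged = TRUE, waveform_noise_sd = 0.1),
      n_pulses = 200, seed = 990 + i)
    evoked_waveform_correlation(tbn$unit, tbn$laser_times)$r
  }, 0)
  expect_true(all(rs > 0.95))

  no_wf <- make_unit(c(1, 2, 3))
  expect_error(evoked_waveform_correlation(no_wf, c(0.5)), "waveforms")
})

test_that("tagging rule is the conjunction of SALT and waveform criteria", {
  rec <- tibble::tibble(
    unit_id = c("a", "b", "c", "d"),
    salt_p = c(0.005, 0.02, 0.005, NA),
    waveform_r = c(0.95, 0.95, 0.80, 0.95))
  out <- identify_tagged_units(rec)
  expect_equal(out$tagged, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("evoked latency reads off the first significant 0.1-ms bin", {
  pulses <- 2 + (0:199) * 2
  spikes <- sort(c(pulses + 0.003, runif(400, 0, 402)))
  lat <- evoked_response_latency(spikes, pulses)
  expect_equal(lat$latency_ms, 3.0)
  expect_lte(lat$latency_ms, lat$peak_ms)

  # tagged simulation: detection onset sits in the rising flank of the
  # jittered evoked response (within 2.5 s.d. before the 3 ms mean) and
  # never past the peak bin
  ok <- vapply(1:10, function(i) {
    tb <- simulate_tagging_block(
      unit_params(baseline_hz = 8, tagged = TRUE), seed = 1090 + i)
    l <- evoked_response_latency(tb$unit$spike_times, tb$laser_times)
    !is.na(l$latency_ms) && l$latency_ms >= 2.2 && l$latency_ms <= 3.1 &&
      l$latency_ms <= l$peak_ms
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  # untagged Poisson unit: no significant bin
  absent <- vapply(1:8, function(i) {
    tb <- simulate_tagging_block(unit_params(baseline_hz = 8),
                                 n_pulses = 300, seed = 1190 + i)
    is.na(evoked_response_latency(tb$unit$spike_times,
                                  tb$laser_times)$latency_ms)
  }, TRUE)
  expect_gte(mean(absent), 0.75)
})

test_that("adding evoked spikes at the true latency cannot delay it", {
  pulses <- 2 + (0:149) * 2
  set.seed(129)
  base <- sort(runif(2000, 0, 302))
  weak <- sort(c(base, pulses[1:100] + 0.004))
  strong <- sort(c(base, pulses + 0.004))
  lw <- evoked_response_latency(weak, pulses)$latency_ms
  ls <- evoked_response_latency(strong, pulses)$latency_ms
  expect_true(is.na(lw) || ls <= lw)
})
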