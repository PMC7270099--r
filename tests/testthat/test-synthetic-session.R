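test_that("degenerate lick probabilities give degenerate outcome rates", {
  cfg <- sim_config(n_trials = 200, p_lick_nogo = 0)
  s <- simulate_behavior(cfg, seed = 11)
  r <- compute_outcome_rates(s$trials)
  expect_equal(r$n_fas, 0)
  expect_equal(r$cr_rate, 1)
})

test_that("Go-trial count falls in the central 99% binomial interval", {
  cfg <- sim_config(n_trials = 400, p_go = 0.5)
  s <- simulate_behavior(cfg, seed = 21)
  n_go <- sum(s$trials$stim == "Go")
  expect_gte(n_go, qbinom(0.005, 400, 0.5))
  expect_lte(n_go, qbinom(0.995, 400, 0.5))
})

test_that("laser flags follow 20-trial blocks and the stimulus scheme", {
  cfg <- sim_config(n_trials = 200, laser_block_len = 20,
                    laser_scheme = "nogo_trials")
  s <- simulate_behavior(cfg, seed = 31)
  block <- (s$trials$index - 1) %/% 20
  on_block <- block %% 2 == 1
  expect_true(all(!s$trials$laser[!on_block]))
  expect_true(all(s$trials$laser == (on_block & s$trials$stim == "No-Go")))
})

test_that("hit/FA trials lick in the answer period; miss/CR never do", {
  cfg <- sim_config(n_trials = 150)
  s <- simulate_behavior(cfg, seed = 41)
  tr <- s$trials
  ans_licks <- findInterval(tr$answer_end, s$licks) -
    findInterval(tr$waiting_end, s$licks)
  licked <- tr$outcome %in% c("hit", "FA")
  expect_true(all(ans_licks[licked] >= 1))
  expect_true(all(ans_licks[!licked] == 0))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_trials = 80, laser_scheme = "go_trials")
  a <- simulate_behavior(cfg, 0.4, seed = 51)
  b <- simulate_behavior(cfg, 0.4, seed = 51)
  expect_identical(a, b)
  ua <- simulate_unit(a, unit_params(baseline_hz = 7), seed = 52)
  ub <- simulate_unit(b, unit_params(baseline_hz = 7), seed = 52)
  expect_identical(ua, ub)
})

test_that("outcome rates converge to configured probabilities at large n", {
  cfg <- sim_config(n_trials = 10000, p_lick_go = 0.9, p_lick_nogo = 0.4)
  s <- simulate_behavior(cfg, seed = 61)
  r <- compute_outcome_rates(s$trials)
  se_hit <- sqrt(0.9 * 0.1 / (r$n_hits + r$n_misses))
  se_fa <- sqrt(0.4 * 0.6 / (r$n_fas + r$n_crs))
  expect_lt(abs(r$hit_rate - 0.9), 3 * se_hit)
  expect_lt(abs(r$fa_rate - 0.4), 3 * se_fa)
})

test_that("median first-lick latency is near 0.45-0.5 s under defaults", {
  cfg <- sim_config(n_trials = 2000)
  s <- simulate_behavior(cfg, seed = 71)
  lat <- lick_latency_summary(s$trials, s$licks)
  expect_gt(lat, 0.40)
  expect_lt(lat, 0.55)
})

test_that("identity gains give baseline rate in every condition", {
  cfg <- sim_config(n_trials = 400)
  s <- simulate_behavior(cfg, seed = 81)
  u <- simulate_unit(s, unit_params(baseline_hz = 10), seed = 82)
  r <- trial_rates(u, s$trials)
  for (cond in unique(r$outcome)) {
    x <- r$rate[r$outcome == cond]
    se <- sqrt(10 / (0.5 * length(x)))   # Poisson s.e. of the mean rate
    expect_lt(abs(mean(x) - 10), 3 * se)
  }
})

test_that("spike counts are Poisson-dispersed under identity gains", {
  cfg <- sim_config(n_trials = 500)
  s <- simulate_behavior(cfg, seed = 91)
  u <- simulate_unit(s, unit_params(baseline_hz = 8), seed = 92)
  counts <- event_window_rate(u$spike_times, s$trials$stim_on, c(0, 0.5)) * 0.5
  disp <- var(counts) / mean(counts)
  n <- length(counts)
  # variance/mean of Poisson counts ~ chi-square_{n-1}/(n-1)
  expect_gt(disp, qchisq(0.005, n - 1) / (n - 1))
  expect_lt(disp, qchisq(0.995, n - 1) / (n - 1))
})

test_that("laser gain scales the waiting-period rate", {
  cfg <- sim_config(n_trials = 1200, laser_scheme = "nogo_trials")
  s <- simulate_behavior(cfg, seed = 101)
  u <- simulate_unit(s, unit_params(baseline_hz = 12, laser_gain = 0.5),
                     seed = 102)
  nogo <- s$trials[s$trials$stim == "No-Go", ]
  on <- event_window_rate(u$spike_times, nogo$stim_on[nogo$laser], c(0, 0.5))
  off <- event_window_rate(u$spike_times, nogo$stim_on[!nogo$laser],
                           c(0, 0.5))
  expect_lt(abs(mean(on) / mean(off) - 0.5), 0.1)
})

test_that("tagging block with reliability 1 and no jitter adds exactly one
           spike per pulse at the set latency", {
  p <- unit_params(baseline_hz = 0, tagged = TRUE, tag_reliability = 1,
                   tag_jitter_s = 0, tag_latency_s = 0.004)
  tb <- simulate_tagging_block(p, n_pulses = 100, seed = 111)
  expect_length(tb$unit$spike_times, 100)
  expect_equal(tb$unit$spike_times, tb$laser_times + 0.004)
  expect_equal(diff(tb$laser_times), rep(2, 99))
})

test_that("untagged post-pulse spike counts match the baseline Poisson rate", {
  p <- unit_params(baseline_hz = 20, tagged = FALSE)
  tb <- simulate_tagging_block(p, n_pulses = 400, seed = 121)
  cnt <- sum(event_window_rate(tb$unit$spike_times, tb$laser_times,
                               c(0, 0.01)) * 0.01)
  expect_gt(cnt, qpois(0.005, 400 * 20 * 0.01))
  expect_lt(cnt, qpois(0.995, 400 * 20 * 0.01))
})

test_that("tuning simulator: flat at kappa 0, laser-neutral at gain 1", {
  rec <- simulate_tuning_session(kappa = 0, peak_hz = 10, baseline_hz = 0,
                                 n_repeats = 60, laser_gain = 1, seed = 131)
  curve <- build_tuning_curve(rec, laser = FALSE)
  se <- sqrt(10 / (2 * 60))
  expect_true(all(abs(curve$mean_rate - 10) < 4 * se))
  on <- mean(rec$rate_hz[rec$laser]); off <- mean(rec$rate_hz[!rec$laser])
  expect_lt(abs(on - off), 4 * sqrt(10 / (2 * 60 * 12)) * sqrt(2))
})

test_that("strong tuning recovers the preferred direction across seeds", {
  hits <- vapply(1:100, function(i) {
    rec <- simulate_tuning_session(pref_direction = 60, kappa = 4,
                                   peak_hz = 20, seed = 1000 + i)
    curve <- build_tuning_curve(rec, laser = FALSE)
    best <- curve$directions[which.max(curve$mean_rate)]
    (best - 60) %% 180 == 0
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("photometry simulator: null signal, unit peak, kernel recovery", {
  tr0 <- simulate_photometry(5, kernel_amplitude = 0, baseline_F = 3,
                             noise_sd = 0, duration_s = 10)
  expect_true(all(tr0$F == 3))

  tr1 <- simulate_photometry(5, kernel_amplitude = 3, baseline_F = 3,
                             noise_sd = 0, duration_s = 10)
  d <- compute_dff(tr1, 5, baseline_window_s = 2)
  expect_equal(peak_response(d)$peak, 1.0)

  ev <- seq(10, 10 * 100, by = 10)
  noise <- 0.05
  trn <- simulate_photometry(ev, kernel_amplitude = 1, baseline_F = 1,
                             noise_sd = noise, seed = 141)
  dn <- compute_dff(trn, ev, baseline_window_s = 2, post_s = 5)
  tru <- simulate_photometry(20, kernel_amplitude = 1, baseline_F = 1,
                             noise_sd = 0, duration_s = 40)
  dt <- compute_dff(tru, 20, baseline_window_s = 2, post_s = 5)
  rms <- sqrt(mean((colMeans(dn$dff) - colMeans(dt$dff))^2))
  expect_lt(rms, 3 * noise / sqrt(100))
})

test_that("invalid generator inputs are rejected", {
  expect_error(sim_config(p_go = 1.5), "probability")
  expect_error(sim_config(waiting_s = -1), "positive")
  expect_error(unit_params(outcome_gain_cr = -0.2), "gains")
  expect_error(simulate_tuning_session(kappa = -1), "kappa")
  expect_error(simulate_photometry(5, 1, fs = 0, duration_s = 10), "fs")
  expect_error(
    simulate_behavior(sim_config(n_trials = 10), learning_level = 2),
    "learning_level")
})
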