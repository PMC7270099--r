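test_that("event_window_rate matches arithmetic and the naive loop oracle", {
  ev <- c(10, 20)
  spikes <- 10 + c(0.05, 0.1, 0.2, 0.3, 0.45)
  expect_equal(event_window_rate(spikes, ev, c(0, 0.5)), c(10, 0))
  expect_equal(event_window_rate(numeric(0), ev, c(0, 0.5)), c(0, 0))
  expect_error(event_window_rate(spikes, ev, c(0.5, 0.5)), "t1 > t0")

  set.seed(5)
  for (i in 1:20) {
    sp <- sort(runif(50, 0, 100))
    evs <- runif(8, 5, 95)
    w <- sort(runif(2, -1, 1))
    if (diff(w) == 0) next
    expect_equal(event_window_rate(sp, evs, w),
                 naive_window_rate(sp, evs, w))
  }

  # boundary convention: [t0, t1) keeps the left edge, drops the right
  expect_equal(event_window_rate(c(10, 10.5), 10, c(0, 0.5)), 2)
})

test_that("Poisson mean rate is recovered within 3 s.e.", {
  set.seed(9)
  span <- 2000
  spikes <- sort(runif(rpois(1, 8 * span), 0, span))
  ev <- seq(2, span - 2, length.out = 500)
  r <- event_window_rate(spikes, ev, c(0, 0.5))
  expect_lt(abs(mean(r) - 8), 3 * sqrt(8 / (0.5 * 500)))
})

test_that("responsiveness filter applies rate floor and signed-rank rules", {
  # mean evoked 0.4 spikes/s (< 0.5) -> excluded by the floor
  tr <- make_trials(rep(c("hit", "CR"), 25))
  spikes <- tr$stim_on[seq(1, 50, by = 5)] + 0.2   # 10 spikes over 50 trials
  u <- make_unit(spikes)
  f <- responsiveness_filter(u, tr, "V1")
  expect_equal(f$evoked_mean, 0.4)
  expect_false(f$included)
  expect_equal(f$reason, "rate_floor")

  # evoked identical to baseline -> degenerate
  u0 <- make_unit(numeric(0))
  f0 <- responsiveness_filter(u0, tr, "V1")
  expect_false(f0$included)
  expect_equal(f0$reason, "degenerate")

  # strongly evoked simulated unit is included in both areas
  cfg <- sim_config(n_trials = 50)
  s <- simulate_behavior(cfg, seed = 23)
  uu <- simulate_unit(s, unit_params(baseline_hz = 2, evoked_gain_go = 10,
                                     evoked_gain_nogo = 10), seed = 24)
  expect_true(responsiveness_filter(uu, s$trials, "V1")$included)
  expect_true(responsiveness_filter(uu, s$trials, "OFC")$included)
})

test_that("selectivity index follows its closed form", {
  expect_equal(compute_selectivity_index(3, 1), 0.5)
  expect_equal(compute_selectivity_index(2, 2), 0)
  expect_equal(compute_selectivity_index(1, 3), -0.5)
  expect_true(is.na(compute_selectivity_index(0, 0)))
  expect_error(compute_selectivity_index(-1, 2), ">= 0")
  # scale invariance
  expect_equal(compute_selectivity_index(3e3, 1e3), 0.5)
})

test_that("modulation index: arithmetic, FA gate, absent cases", {
  tr <- make_trials(c(rep("CR", 4), rep("FA", 4)))
  sp <- c(tr$stim_on[1:2] + 0.1,                       # CR rates 2,2,0,0
          rep(tr$stim_on[5:6], each = 2) + c(0.1, 0.3),
          tr$stim_on[7:8] + 0.2)                       # FA rates 4,4,2,2
  u <- make_unit(sp)
  mi <- compute_modulation_index(u, tr, min_fa_trials = 0)
  expect_equal(mi$num_mean, 1)
  expect_equal(mi$den_mean, 3)
  expect_equal(mi$value, -0.5)

  # FA-count gate: 12 FA trials is not enough
  tr2 <- make_trials(c(rep("CR", 20), rep("FA", 12)))
  u2 <- make_unit(tr2$stim_on + 0.1)
  mi2 <- compute_modulation_index(u2, tr2)
  expect_false(mi2$included)
  expect_equal(mi2$reason, "fa_count")

  # no CR trials -> absent value
  tr3 <- make_trials(rep("FA", 20))
  mi3 <- compute_modulation_index(u2, tr3)
  expect_true(is.na(mi3$value))
})

test_that("response index hits its boundary and identity cases", {
  # spikes only in baseline -> RI = -1
  tr <- make_trials(rep("hit", 10))
  u <- make_unit(tr$stim_on - 0.1)
  ri <- compute_response_index(u, tr, "hit")
  expect_equal(ri$value, -1)

  # equal mean rates in both windows -> RI = 0: per trial 1 baseline spike
  # (5 Hz over 0.2 s) and 2 or 3 evoked spikes (mean 2.5 over 0.5 s = 5 Hz)
  ev_sp <- c(rep(tr$stim_on[1:5], each = 2) + c(0.1, 0.3),
             rep(tr$stim_on[6:10], each = 3) + c(0.1, 0.25, 0.4))
  u2 <- make_unit(c(tr$stim_on - 0.1, ev_sp))
  ri2 <- compute_response_index(u2, tr, "hit")
  expect_equal(ri2$num_mean, 5)
  expect_equal(ri2$den_mean, 5)
  expect_equal(ri2$value, 0)

  ri3 <- compute_response_index(u, tr, "CR")
  expect_false(ri3$included)
})

test_that("ratio indices are bounded and antisymmetric", {
  set.seed(13)
  for (i in 1:50) {
    a <- runif(1, 0, 20); b <- runif(1, 0, 20)
    v <- compute_selectivity_index(a, b)
    expect_lte(abs(v), 1)
    expect_equal(compute_selectivity_index(b, a), -v)
  }
})

test_that("early/late split isolates a late-only outcome gain", {
  cfg <- sim_config(n_trials = 400, p_lick_nogo = 0.5)
  s <- simulate_behavior(cfg, seed = 33)
  vals <- t(vapply(1:40, function(i) {
    u <- simulate_unit(s, unit_params(baseline_hz = 10,
                                      outcome_gain_cr = 0.6,
                                      outcome_gain_fa = 1.0), seed = 330 + i)
    el <- early_late_indices(u, s$trials)
    c(el$early$mi$value, el$late$mi$value)
  }, c(0, 0)))
  expect_lt(abs(mean(vals[, 1])), 0.06)
  expect_lt(abs(mean(vals[, 2]) - (0.6 - 1) / (0.6 + 1)), 0.06)

  # stationary unit: early and late indices are 0 in expectation
  u0 <- simulate_unit(s, unit_params(baseline_hz = 15), seed = 34)
  el0 <- early_late_indices(u0, s$trials)
  expect_lt(abs(el0$late$si$value), 0.1)

  # no spikes at all in the early window -> absent early index
  tr <- make_trials(c("hit", "CR", "FA"))
  ue <- make_unit(tr$stim_on + 0.3)
  ele <- early_late_indices(ue, tr)
  expect_true(is.na(ele$early$si$value))
})

test_that("rate change follows both conventions", {
  expect_equal(rate_change(1.2, 1.0, "relative"), 0.2, tolerance = 1e-12)
  expect_equal(rate_change(0.5, 1.0, "symmetric"), -1 / 3)
  expect_true(is.na(rate_change(1, 0, "relative")))
})

test_that("laser rate change gates FA sessions on both laser conditions", {
  cfg <- sim_config(n_trials = 600, laser_scheme = "nogo_trials",
                    p_lick_nogo = 0.5)
  s <- simulate_behavior(cfg, seed = 43)
  u <- simulate_unit(s, unit_params(baseline_hz = 10, laser_gain = 0.6),
                     seed = 44)
  rc <- laser_rate_change(u, s$trials, "relative", "cr")
  expect_lt(abs(rc$value - (-0.4)), 0.15)

  # too few FA trials in a laser condition -> excluded
  few <- s$trials
  drop <- which(few$outcome == "FA" & few$laser)
  few$outcome[drop[-(1:5)]] <- "CR"
  rc2 <- laser_rate_change(u, few, "relative", "fa")
  expect_false(rc2$included)
  expect_equal(rc2$reason, "fa_count")
})

test_that("population PSTH normalizes by the across-condition peak", {
  tr <- make_trials(c(rep("hit", 10), rep("CR", 10)))
  hit_on <- tr$stim_on[tr$outcome == "hit"]
  cr_on <- tr$stim_on[tr$outcome == "CR"]
  # 10 Hz peak bin in hit trials, 5 Hz in CR trials (bin = 10 ms)
  sp <- c(hit_on + 0.205, cr_on[1:5] + 0.205)
  u <- make_unit(sp)
  p <- normalized_population_psth(list(u), tr, "outcome",
                                  window = c(0, 0.5), bin_s = 0.01)
  peak_hit <- max(p$rate[p$condition == "hit"])
  peak_cr <- max(p$rate[p$condition == "CR"])
  expect_equal(peak_hit, 1.0)
  expect_equal(peak_cr, 0.5)

  # identical conditions give identical normalized curves
  sp2 <- c(hit_on + 0.105, cr_on + 0.105)
  u2 <- make_unit(sp2)
  p2 <- normalized_population_psth(list(u2), tr, "outcome",
                                   window = c(0, 0.5), bin_s = 0.01)
  expect_equal(p2$rate[p2$condition == "hit"],
               p2$rate[p2$condition == "CR"])

  # a silent unit is dropped with a message
  expect_message(
    normalized_population_psth(list(u, make_unit(numeric(0))), tr,
                               "outcome", window = c(0, 0.5)),
    "no spikes")
})

test_that("CR-suppressed population PSTH is below FA in the late window", {
  cfg <- sim_config(n_trials = 300, p_lick_nogo = 0.5)
  s <- simulate_behavior(cfg, seed = 53)
  units <- lapply(1:12, function(i) {
    simulate_unit(s, unit_params(baseline_hz = 12, outcome_gain_cr = 0.5,
                                 outcome_gain_fa = 1.2),
                  seed = 530 + i, unit_id = paste0("u", i))
  })
  p <- normalized_population_psth(units, s$trials, "outcome",
                                  window = c(0, 0.5), bin_s = 0.05)
  late <- p$t >= 0.1
  cr <- mean(p$rate[p$condition == "CR" & late])
  fa <- mean(p$rate[p$condition == "FA" & late])
  expect_lt(cr, fa)
})
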