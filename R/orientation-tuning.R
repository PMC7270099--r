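# Passive-viewing orientation-tuning analysis: per-direction tuning curves
# from drifting-period rates, the circular-moment orientation selectivity
# index (OSI), a visual-responsiveness t statistic, and the inclusion rule
# applied before laser rate-change comparisons.

#' Build a tuning curve from a tuning recording
#'
#' Per-direction mean of the drifting-period rate over repeats, for one laser
#' condition.
#'
#' @param recording A `tuning_recording` tibble (direction_deg, rep, laser,
#'   rate_hz), e.g. from [simulate_tuning_session()].
#' @param laser Logical: which laser condition to extract.
#' @return List of class `tuning_curve`: directions (deg), mean_rate,
#'   repeats (directions x repeats matrix), laser, n_repeats.
#' @export
build_tuning_curve <- function(recording, laser = FALSE) {
  d <- recording[recording$laser == laser, ]
  dirs <- sort(unique(recording$direction_deg))
  reps <- lapply(dirs, function(th) d$rate_hz[d$direction_deg == th])
  n <- vapply(reps, length, 0L)
  if (any(n == 0)) {
    stop("no repeats for direction(s): ",
         paste(dirs[n == 0], collapse = ", "))
  }
  nr <- min(n)
  mat <- do.call(rbind, lapply(reps, function(x) x[seq_len(nr)]))
  structure(
    list(directions = dirs, mean_rate = vapply(reps, mean, 0),
         repeats = mat, laser = laser, n_repeats = nr),
    class = "tuning_curve")
}

#' Global orientation selectivity index
#'
#' OSI = sqrt((sum_i R(theta_i) sin(2 theta_i))^2 +
#' (sum_i R(theta_i) cos(2 theta_i))^2) / sum_i R(theta_i): the modulus of
#' the doubled-angle (orientation-space) circular resultant of the tuning
#' curve. 0 for a flat curve, 1 for a response confined to one orientation.
#'
#' @param curve A `tuning_curve`, or a numeric vector of rates (then
#'   `directions_deg` is required).
#' @param directions_deg Directions in degrees, matching `curve` when it is a
#'   plain vector.
#' @return OSI in \[0, 1\], or `NA` for an all-zero curve.
#' @export
compute_osi <- function(curve, directions_deg = NULL) {
  if (inherits(curve, "tuning_curve")) {
    r <- curve$mean_rate
    th <- curve$directions
  } else {
    r <- curve
    th <- directions_deg
    if (is.null(th)) stop("directions_deg required for a plain rate vector")
  }
  if (any(r < 0)) stop("rates must be >= 0")
  s <- sum(r)
  if (s == 0) return(NA_real_)
  a <- th * pi / 180
  sqrt(sum(r * sin(2 * a))^2 + sum(r * cos(2 * a))^2) / s
}

#' Visual-responsiveness t statistic
#'
#' Mean evoked rate divided by its s.e.m. across repeats at the preferred
#' direction (the argmax of the mean tuning curve; ties broken by the lower
#' direction index). Computed on laser-off data by convention.
#'
#' @param curve A `tuning_curve`.
#' @return List: t_stat (`NA` with reason "zero_sem" when the s.e.m. is 0),
#'   pref_direction, reason.
#' @export
responsiveness_t <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  i <- which.max(curve$mean_rate)
  reps <- curve$repeats[i, ]
  if (length(reps) < 2) stop("need >= 2 repeats at the preferred direction")
  sem <- stats::sd(reps) / sqrt(length(reps))
  if (sem == 0) {
    return(list(t_stat = NA_real_, pref_direction = curve$directions[i],
                reason = "zero_sem"))
  }
  list(t_stat = mean(reps) / sem, pref_direction = curve$directions[i],
       reason = "ok")
}

#' Tuning-analysis inclusion rule
#'
#' A unit enters tuning/laser analyses only when, in the laser-off condition,
#' OSI > 0.08 (orientation sensitive), t > 2 (visually responsive), and the
#' peak evoked rate exceeds 2 Hz.
#'
#' @param curve_off Laser-off `tuning_curve`.
#' @param osi_min,t_min,peak_min_hz Thresholds (defaults 0.08, 2, 2).
#' @return List of class `tuning_inclusion`: osi, t_stat, peak_rate,
#'   included, failed (character vector of failing criteria).
#' @export
tuning_inclusion <- function(curve_off, osi_min = 0.08, t_min = 2,
                             peak_min_hz = 2) {
  osi <- compute_osi(curve_off)
  tt <- responsiveness_t(curve_off)
  peak <- max(curve_off$mean_rate)
  failed <- character(0)
  if (is.na(osi) || osi <= osi_min) failed <- c(failed, "osi")
  if (is.na(tt$t_stat) || tt$t_stat <= t_min) failed <- c(failed, "t_stat")
  if (peak <= peak_min_hz) failed <- c(failed, "peak_rate")
  structure(
    list(osi = osi, t_stat = tt$t_stat, peak_rate = peak,
         included = length(failed) == 0, failed = failed),
    class = "tuning_inclusion")
}

#' Laser rate-change index on tuning data
#'
#' Symmetric rate change (on - off)/(on + off) between laser conditions,
#' with rates averaged over all orientations.
#'
#' @param recording A `tuning_recording`.
#' @return Numeric rate-change index.
#' @export
tuning_laser_rate_change <- function(recording) {
  on <- mean(recording$rate_hz[recording$laser])
  off <- mean(recording$rate_hz[!recording$laser])
  rate_change(on, off, "symmetric")
}
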