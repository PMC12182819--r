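# Stroke volume, cardiac output, regurgitant fraction, pulmonary transit
# time and pulmonary blood volume from time-series inputs.

# split a sampled flow curve into beats: explicit boundaries win, then a
# heart-rate grid, then threshold up-crossing detection.
.beat_windows <- function(time_s, flow, beat_starts_s = NULL, hr_bpm = NULL) {
  if (!is.null(beat_starts_s)) {
    b <- beat_starts_s
  } else if (!is.null(hr_bpm)) {
    t_beat <- 60 / hr_bpm
    b <- seq(min(time_s), max(time_s) + 1e-9, by = t_beat)
  } else {
    thr <- 0.05 * max(flow)
    up <- which(flow[-1] > thr & flow[-length(flow)] <= thr) + 1L
    if (length(up) < 2L)
      stop_lungecv("no complete beat found in the flow curve")
    b <- time_s[up]
  }
  if (length(b) < 2L) stop_lungecv("no complete beat found in the flow curve")
  b
}

#' Stroke volume from a flow curve
#'
#' Trapezoidal integral of flow over each complete beat, averaged across
#' beats.
#'
#' @param flow a [simulate_flow()] object, or a data frame with `time_s` and
#'   `flow_ml_s`.
#' @param beat_starts_s optional beat boundary times (s); taken from the
#'   object when present.
#' @param hr_bpm optional heart rate used to grid beats when no boundaries
#'   are given.
#' @return stroke volume in mL.
#' @export
stroke_volume <- function(flow, beat_starts_s = NULL, hr_bpm = NULL) {
  if (inherits(flow, "flow_curve")) {
    beat_starts_s <- beat_starts_s %||% flow$beat_starts_s
    hr_bpm <- hr_bpm %||% flow$hr_bpm
    flow <- flow$flow
  }
  t <- flow$time_s; q <- flow$flow_ml_s
  b <- .beat_windows(t, q, beat_starts_s, hr_bpm)
  sv <- vapply(seq_len(length(b) - 1L), function(i) {
    sel <- t >= b[i] - 1e-9 & t <= b[i + 1] + 1e-9
    if (sum(sel) < 3L) return(NA_real_)
    trapz_int(t[sel], q[sel])
  }, numeric(1))
  sv <- sv[is.finite(sv)]
  if (length(sv) == 0L) stop_lungecv("no complete beat found in the flow curve")
  mean(sv)
}

#' Cardiac output
#'
#' @param sv_ml stroke volume (mL).
#' @param hr_bpm heart rate (beats/min).
#' @return cardiac output in L/min.
#' @export
cardiac_output <- function(sv_ml, hr_bpm) sv_ml * hr_bpm / 1000

#' Mitral regurgitant fraction
#'
#' `(SV_LV - SV_aorta) / SV_LV`: the share of the left-ventricular stroke
#' volume that does not reach the aorta.
#'
#' @param sv_lv_ml left-ventricular stroke volume (mL), must be positive.
#' @param sv_aorta_ml aortic (forward) stroke volume (mL).
#' @return regurgitant fraction; negative values are flagged with a warning.
#' @export
regurgitant_fraction <- function(sv_lv_ml, sv_aorta_ml) {
  if (sv_lv_ml <= 0) stop_lungecv("LV stroke volume must be positive")
  rf <- (sv_lv_ml - sv_aorta_ml) / sv_lv_ml
  if (rf < 0) {
    warning("negative regurgitant fraction flagged", call. = FALSE)
    attr(rf, "flagged") <- TRUE
  }
  rf
}

#' Left-ventricular stroke volume from a volume curve
#'
#' End-diastolic minus end-systolic volume.
#'
#' @param lv_volume data frame with `time_s` and `volume_ml`.
#' @return stroke volume in mL.
#' @export
lv_stroke_volume <- function(lv_volume) {
  max(lv_volume$volume_ml) - min(lv_volume$volume_ml)
}

# gamma-variate fit of a single first-pass curve; returns the fitted first
# moment (centroid) in seconds. Baseline is the pre-arrival level,
# recirculation is excluded by truncating at 50% of the peak on the
# down-slope before fitting. Only (K, alpha, beta) are genuinely free: the
# arrival time t0 is profiled on a grid, with the remaining parameters
# solved by weighted log-linear least squares at each candidate (weights
# y^2, the standard variance-stabilizing choice for log-linearized
# gamma-variate fits); a bounded Levenberg-Marquardt refinement is accepted
# only when it improves the residual, which keeps noisy, coarsely sampled
# curves from driving the moment off the data support.
.gamma_moment <- function(time_s, y) {
  peak_i <- which.max(y)
  if (peak_i < 3L) stop_lungecv("no pre-bolus baseline before the peak")
  # pre-arrival baseline: average everything before the sustained rise
  # (an unbiased estimate, unlike order-statistic baselines)
  lo <- min(y[seq_len(peak_i)])
  thr <- lo + 0.3 * (y[peak_i] - lo)
  sustained <- which(y > thr & c(y[-1] > thr, TRUE))  # two consecutive above
  arr <- sustained[sustained <= peak_i][1]
  if (is.na(arr)) arr <- peak_i
  baseline <- if (arr >= 4L) mean(y[seq_len(arr - 2L)]) else
    mean(y[seq_len(max(arr - 1L, 2L))])
  yc <- y - baseline
  peak <- yc[peak_i]
  if (peak <= 0) stop_lungecv("no first-pass peak above baseline")
  # truncate at 50% of peak on the down-slope
  after <- seq(peak_i, length(yc))
  below <- after[yc[after] < 0.5 * peak]
  last_i <- if (length(below)) below[1] else length(yc)
  sel <- seq_len(last_i)
  tt <- time_s[sel]; yy <- yc[sel]
  use <- which(yy > 0.05 * peak & seq_along(yy) <= last_i)
  use <- use[use >= suppressWarnings(min(which(yy > 0.2 * peak))) - 2L]
  use <- use[use >= 1L]
  if (length(use) < 4L) stop_lungecv("too few samples for a gamma-variate fit")
  t_use <- tt[use]; y_use <- yy[use]
  w <- y_use^2

  # the whole truncated segment (including pre-arrival near-zero samples)
  # enters the nonlinear residual: the model predicts 0 before t0, which
  # pins the arrival time and rise
  gamma_rss <- function(k, alpha, beta, t0) {
    u <- pmax(tt - t0, 0)
    sum((yy - k * u^alpha * exp(-u / beta))^2)
  }
  moment_of <- function(p) p$t0 + p$beta * (p$alpha + 1)
  # unimodality constraint on the centroid: for a gamma-variate the first
  # moment exceeds the peak time by beta, and the half-decay width x_half
  # is between about 1.2*beta and 3.5*beta across physiological shapes
  # (alpha in [0.5, 25]); the admissible centroid window follows from the
  # observed peak and 50%-crossing times, padded by one frame interval
  frame <- stats::median(diff(time_s))
  tp_obs <- tt[peak_i]
  x_half <- max(time_s[min(last_i, length(time_s))] - tp_obs, frame)
  m_window <- c(tp_obs - frame + x_half / 4,
                tp_obs + frame + x_half / 1.2)
  # profile t0: weighted log-linear solve per candidate; degenerate or
  # off-support candidates are rejected, not clamped
  solve_t0 <- function(t0) {
    u <- t_use - t0
    if (any(u <= 0)) return(NULL)
    X <- cbind(1, log(u), -u)
    co <- tryCatch(stats::lm.wfit(X, log(y_use), w)$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || anyNA(co) || co[2] <= 0 || co[3] <= 0) return(NULL)
    p <- list(k = exp(co[1]), alpha = co[2], beta = 1 / co[3], t0 = t0)
    m <- moment_of(p)
    if (m < m_window[1] || m > m_window[2]) return(NULL)
    p
  }
  t0_grid <- seq(time_s[1], t_use[1] - 1e-6, length.out = 80L)
  best <- NULL; best_rss <- Inf
  for (t0 in t0_grid) {
    p <- solve_t0(t0)
    if (is.null(p)) next
    rss <- gamma_rss(p$k, p$alpha, p$beta, p$t0)
    if (is.finite(rss) && rss < best_rss) { best <- p; best_rss <- rss }
  }
  if (is.null(best)) {
    # heuristic start from the peak position when every log-linear solve
    # is degenerate (e.g. hardly any usable down-slope)
    tp <- t_use[which.max(y_use)]
    t0h <- max(time_s[1], t_use[1] - 1.5)
    best <- list(k = max(y_use) / max(tp - t0h, 0.5)^3 * exp(3), alpha = 3,
                 beta = max((tp - t0h) / 3, 0.3), t0 = t0h)
    best_rss <- gamma_rss(best$k, best$alpha, best$beta, best$t0)
  }
  # refinement on the full truncated segment; accepted only when it improves
  # the residual and keeps the moment on the data support
  refine <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      yy ~ k * pmax(tt - t0, 0)^alpha * exp(-pmax(tt - t0, 0) / beta),
      start = best[c("k", "alpha", "beta", "t0")],
      lower = c(k = 0, alpha = 0.2, beta = 0.05, t0 = time_s[1]),
      upper = c(k = Inf, alpha = 25, beta = 30, t0 = t_use[1]),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (!is.null(refine)) {
    p <- as.list(stats::coef(refine))
    m <- moment_of(p)
    if (m >= m_window[1] && m <= m_window[2] &&
        gamma_rss(p$k, p$alpha, p$beta, p$t0) < best_rss) best <- p
  }
  moment <- moment_of(best)
  if (moment < time_s[1] || moment > max(time_s))
    stop_lungecv("gamma-variate moment outside the sampled window")
  moment
}

#' Pulmonary transit time from first-pass curves
#'
#' Gamma-variate fits to the baseline-subtracted, recirculation-truncated
#' right- and left-ventricular first-pass curves; the transit time is the
#' difference of the fitted first moments (bolus centroids).
#'
#' @param curves a [simulate_first_pass()] object or data frame with
#'   `time_s`, `rv`, `lv`.
#' @return pulmonary transit time in seconds.
#' @export
pulmonary_transit_time <- function(curves) {
  m_rv <- .gamma_moment(curves$time_s, curves$rv)
  m_lv <- .gamma_moment(curves$time_s, curves$lv)
  m_lv - m_rv
}

#' Pulmonary blood volume
#'
#' `PBV = pulmonary transit time x cardiac output`, with cardiac output
#' converted to mL/s.
#'
#' @param ptt_s pulmonary transit time (s).
#' @param co_l_min cardiac output (L/min).
#' @return pulmonary blood volume in mL.
#' @export
pulmonary_blood_volume <- function(ptt_s, co_l_min) {
  if (ptt_s < 0 || co_l_min < 0) stop_lungecv("inputs must be nonnegative")
  ptt_s * co_l_min * 1000 / 60
}
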