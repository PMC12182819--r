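#' Forward-simulate a post-contrast T1 volume
#'
#' Fast-exchange single-pool relaxation: all water in a voxel shares one
#' effective rate, so each agent adds `r1 * C * (accessible water fraction)`
#' to the voxel R1, where the accessible fraction is measured against the
#' total voxel water `f_ic + f_ev + f_pl`. Gadolinium chelate accesses
#' `f_ev + f_pl`, ferumoxytol only `f_pl`; in the blood pool both reduce to
#' `1 - hematocrit` because plasma water is `1 - hematocrit` of blood water.
#'
#' @param map a [compartment_map()].
#' @param phase a [contrast_phase()].
#' @param native_r1_tissue,native_r1_blood native longitudinal relaxation
#'   rates (1/ms) for non-blood tissue and the blood pool. Defaults
#'   reproduce native lung T1 of 931 ms and blood T1 of 1199 ms.
#' @return list with `t1` (ms, `NA` where undefined), `r1` (1/ms), and
#'   `valid` (logical; `FALSE` for water-free voxels, where T1 is undefined).
#' @export
simulate_t1_volume <- function(map, phase,
                               native_r1_tissue = 1 / 931,
                               native_r1_blood = 1 / 1199) {
  stopifnot(inherits(map, "compartment_map"), inherits(phase, "contrast_phase"))
  if (native_r1_tissue <= 0 || native_r1_blood <= 0)
    stop_lungecv("native R1 values must be positive")
  water <- map$f_ic + map$f_ev + map$f_pl
  valid <- water > 0
  r1 <- array(native_r1_tissue, dim = map$dim)
  r1[map$blood_mask] <- native_r1_blood
  # relaxivities from L/mmol/s to L/mmol/ms
  kg <- phase$r1_gd / 1000 * (phase$conc_gd + phase$residual_gd)
  kf <- phase$r1_fe / 1000 * phase$conc_fe
  acc_gd <- array(0, dim = map$dim)
  acc_fe <- array(0, dim = map$dim)
  acc_gd[valid] <- (map$f_ev + map$f_pl)[valid] / water[valid]
  acc_fe[valid] <- map$f_pl[valid] / water[valid]
  r1 <- r1 + kg * acc_gd + kf * acc_fe
  t1 <- array(NA_real_, dim = map$dim)
  t1[valid] <- 1 / r1[valid]
  list(t1 = t1, r1 = r1, valid = valid)
}

#' SASHA acquisition settings
#'
#' The study protocol samples saturation times 104, 200 and 374 ms with
#' 8, 4 and 4 averages, plus (optionally) one effectively fully recovered
#' anchor image.
#'
#' @param ts_ms saturation times (ms).
#' @param averages number of averages per saturation time.
#' @param snr signal-to-noise ratio of a single average at the fully
#'   recovered lung signal (`Inf` = noiseless).
#' @param anchor include a long-TS fully recovered anchor sample.
#' @param anchor_ts_ms saturation time used for the anchor.
#' @param b saturation efficiency of the forward model (1 = ideal).
#' @return list of acquisition settings.
#' @export
sasha_protocol <- function(ts_ms = c(104, 200, 374), averages = c(8, 4, 4),
                           snr = Inf, anchor = TRUE, anchor_ts_ms = 10000,
                           b = 1) {
  stopifnot(length(ts_ms) == length(averages))
  if (any(ts_ms <= 0)) stop_lungecv("saturation times must be positive")
  if (!is.infinite(snr) && snr <= 0) stop_lungecv("SNR must be positive")
  if (anchor) {
    ts_ms <- c(ts_ms, anchor_ts_ms)
    averages <- c(averages, 1L)
  }
  list(ts_ms = as.numeric(ts_ms), averages = as.integer(averages),
       snr = snr, b = b)
}

#' Simulate a saturation-recovery (SASHA) image series
#'
#' Per voxel the ideal signal is `S(TS) = A (1 - B exp(-TS/T1))` with `A`
#' proportional to the voxel water content. Each average receives complex
#' Gaussian noise and is magnitude-reconstructed (Rician); the stored frame
#' is the mean of the per-average magnitudes. The single-average noise SD is
#' `sigma = S_ref / snr`, referenced to the fully recovered lung signal
#' (mean `A` over `lung_mask` when given, otherwise the volume maximum).
#'
#' @param t1_volume T1 array in ms (e.g. from [simulate_t1_volume()]`$t1`);
#'   `NA` voxels produce zero signal.
#' @param a_volume proton-content amplitude array `A` (typically the water
#'   fraction `f_ic + f_ev + f_pl`).
#' @param acquisition a [sasha_protocol()].
#' @param lung_mask optional logical array defining the SNR reference.
#' @param seed integer seed for the noise stream.
#' @return object of class `sasha_series`: list with `frames` (4D array,
#'   last dimension indexes saturation time), `ts_ms`, `averages`,
#'   `noise_sd` (single-average sigma; 0 when noiseless), and `b`.
#' @export
simulate_sasha_series <- function(t1_volume, a_volume,
                                  acquisition = sasha_protocol(),
                                  lung_mask = NULL, seed = NULL) {
  stopifnot(identical(dim(t1_volume), dim(a_volume)))
  dm <- dim(t1_volume)
  k <- length(acquisition$ts_ms)
  t1 <- t1_volume
  bad <- !is.finite(t1) | t1 <= 0
  t1[bad] <- 1           # placeholder, signal zeroed below
  a <- a_volume
  a[bad] <- 0
  s_ref <- if (!is.null(lung_mask)) mean(a_volume[lung_mask]) else
    max(a_volume, na.rm = TRUE)
  sigma <- if (is.infinite(acquisition$snr)) 0 else s_ref / acquisition$snr
  frames <- array(0, dim = c(dm, k))
  with_seed(seed, {
    for (i in seq_len(k)) {
      s <- a * (1 - acquisition$b * exp(-acquisition$ts_ms[i] / t1))
      if (sigma > 0) {
        n_avg <- acquisition$averages[i]
        acc <- array(0, dim = dm)
        for (j in seq_len(n_avg)) {
          re <- s + array(stats::rnorm(prod(dm), sd = sigma), dim = dm)
          im <- array(stats::rnorm(prod(dm), sd = sigma), dim = dm)
          acc <- acc + sqrt(re^2 + im^2)
        }
        s <- acc / n_avg
      }
      frames[, , , i] <- s
    }
  })
  structure(list(frames = frames, ts_ms = acquisition$ts_ms,
                 averages = acquisition$averages, noise_sd = sigma,
                 b = acquisition$b),
            class = "sasha_series")
}

#' @export
print.sasha_series <- function(x, ...) {
  cat("sasha_series:", paste(dim(x$frames)[1:3], collapse = " x "),
      "voxels,", length(x$ts_ms), "saturation times\n")
  cat("  TS (ms):", paste(x$ts_ms, collapse = ", "),
      " averages:", paste(x$averages, collapse = ", "),
      " noise sd:", signif(x$noise_sd, 3), "\n")
  invisible(x)
}

#' Simulate a proton-density lung water volume
#'
#' Signal is proportional to per-voxel water content (`f_ic + f_ev + f_pl`),
#' multiplied by a smooth low-order polynomial coil-shading field, with
#' optional Rician noise. Body soft tissue carries 70% water by
#' construction of the phantom, which is what the downstream density
#' normalization assumes.
#'
#' @param map a [compartment_map()].
#' @param shading named list with `order` (polynomial degree) and `coef`
#'   (coefficients over the monomial basis of [poly_basis()], scaled so the
#'   field stays positive), or `NULL` for no shading.
#' @param noise_sd Rician noise sigma relative to unit water signal.
#' @param seed integer seed.
#' @return list with `pd` (signal array), `field` (applied shading field).
#' @export
simulate_proton_density <- function(map, shading = NULL, noise_sd = 0,
                                    seed = NULL) {
  stopifnot(inherits(map, "compartment_map"))
  water <- map$f_ic + map$f_ev + map$f_pl
  field <- array(1, dim = map$dim)
  if (!is.null(shading)) {
    X <- poly_basis(map$dim, shading$order)
    f <- as.vector(X %*% shading$coef)
    if (any(f <= 0)) stop_lungecv("shading field must stay positive")
    field <- array(f, dim = map$dim)
  }
  pd <- water * field
  if (noise_sd > 0) {
    pd <- with_seed(seed, {
      re <- pd + array(stats::rnorm(prod(map$dim), sd = noise_sd),
                       dim = map$dim)
      im <- array(stats::rnorm(prod(map$dim), sd = noise_sd), dim = map$dim)
      sqrt(re^2 + im^2)
    })
  }
  list(pd = pd, field = field)
}

# gamma-variate bolus shape: K (t-t0)^alpha exp(-(t-t0)/beta), 0 before t0,
# normalized to unit peak. First moment about t = t0 + beta (alpha + 1).
gamma_variate <- function(t, t0, alpha, beta) {
  u <- pmax(t - t0, 0)
  tp <- alpha * beta
  y <- (u / tp)^alpha * exp((tp - u) / beta)
  y[u == 0] <- 0
  y
}

#' Simulate first-pass indicator-dilution curves
#'
#' The right-ventricular curve is a gamma-variate bolus; the
#' left-ventricular curve is the same shape delayed by the true pulmonary
#' transit time, so the difference of first moments equals `ptt_s` exactly.
#' An optional recirculation bump and Gaussian noise (peak contrast-to-noise
#' ratio `cnr`) emulate acquired data.
#'
#' @param ptt_s true pulmonary transit time (s).
#' @param frame_s sampling (frame) interval (s); must be at most `ptt_s / 3`.
#' @param duration_s length of the acquisition (s).
#' @param t0_s bolus arrival time in the right ventricle (s).
#' @param alpha,beta gamma-variate shape and scale.
#' @param baseline pre-contrast signal offset (a.u.).
#' @param cnr peak-to-noise ratio (`Inf` = noiseless).
#' @param recirculation amplitude of a delayed, broadened second pass
#'   relative to the first-pass peak (0 disables).
#' @param seed integer seed.
#' @return object of class `first_pass_curves`: data frame columns `time_s`,
#'   `rv`, `lv`, plus attributes `frame_s` and `ptt_true_s`.
#' @export
simulate_first_pass <- function(ptt_s, frame_s = 1.5, duration_s = 45,
                                t0_s = 5, alpha = 3, beta = 1.5,
                                baseline = 0.1, cnr = Inf,
                                recirculation = 0.15, seed = NULL) {
  if (ptt_s <= 0) stop_lungecv("ptt_s must be positive")
  if (frame_s > ptt_s / 3)
    stop_lungecv("sampling interval must be at most ptt_s / 3")
  t <- seq(0, duration_s, by = frame_s)
  shape <- function(t0) {
    y <- gamma_variate(t, t0, alpha, beta)
    if (recirculation > 0)
      y <- y + recirculation * gamma_variate(t, t0 + 12, alpha, 2.5 * beta)
    y
  }
  rv <- baseline + shape(t0_s)
  lv <- baseline + shape(t0_s + ptt_s)
  if (!is.infinite(cnr)) {
    sd <- 1 / cnr
    noise <- with_seed(seed, stats::rnorm(2 * length(t), sd = sd))
    rv <- rv + noise[seq_along(t)]
    lv <- lv + noise[length(t) + seq_along(t)]
  }
  structure(data.frame(time_s = t, rv = rv, lv = lv),
            frame_s = frame_s, ptt_true_s = ptt_s,
            class = c("first_pass_curves", "data.frame"))
}

#' Simulate a periodic flow waveform and paired LV volume curve
#'
#' Aortic forward flow integrates per beat to the aortic stroke volume
#' `sv_ml * (1 - rf)`; the left-ventricular volume curve spans the total
#' stroke volume `sv_ml` between end-diastole and end-systole, so the
#' encoded mitral regurgitant fraction is recoverable downstream.
#'
#' @param sv_ml total left-ventricular stroke volume per beat (mL).
#' @param hr_bpm heart rate (beats per minute).
#' @param rf mitral regurgitant fraction in `[0, 1)`.
#' @param waveform `"smooth"` (sin^2 systolic lobe, C1-continuous) or
#'   `"halfsine"`.
#' @param n_beats number of beats to synthesize.
#' @param points_per_beat temporal sampling density.
#' @param esv_ml end-systolic LV volume (mL) anchoring the volume curve.
#' @param noise_sd additive Gaussian noise on the flow samples (mL/s).
#' @param seed integer seed.
#' @return object of class `flow_curve`: list with `flow` (data frame
#'   `time_s`, `flow_ml_s`), `lv_volume` (data frame `time_s`, `volume_ml`),
#'   `hr_bpm`, `beat_starts_s`, and the encoded `sv_aorta_ml`, `sv_lv_ml`.
#' @export
simulate_flow <- function(sv_ml, hr_bpm, rf = 0,
                          waveform = c("smooth", "halfsine"),
                          n_beats = 5, points_per_beat = 60,
                          esv_ml = 40, noise_sd = 0, seed = NULL) {
  if (sv_ml <= 0) stop_lungecv("stroke volume must be positive")
  if (rf < 0 || rf >= 1) stop_lungecv("regurgitant fraction must be in [0, 1)")
  waveform <- match.arg(waveform)
  t_beat <- 60 / hr_bpm
  t_sys <- 0.35 * t_beat
  sv_aorta <- sv_ml * (1 - rf)
  dt <- t_beat / points_per_beat
  t <- seq(0, n_beats * t_beat, by = dt)
  tb <- t %% t_beat
  in_sys <- tb < t_sys
  flow <- numeric(length(t))
  if (waveform == "smooth") {
    # integral of sin^2 lobe over systole = Qmax * t_sys / 2
    qmax <- 2 * sv_aorta / t_sys
    flow[in_sys] <- qmax * sin(pi * tb[in_sys] / t_sys)^2
  } else {
    qmax <- pi * sv_aorta / (2 * t_sys)
    flow[in_sys] <- qmax * sin(pi * tb[in_sys] / t_sys)
  }
  if (noise_sd > 0)
    flow <- flow + with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  # LV volume: ejection during systole, smooth refill during diastole
  vol <- numeric(length(t))
  edv <- esv_ml + sv_ml
  eject <- 0.5 * (1 - cos(pi * tb[in_sys] / t_sys))
  vol[in_sys] <- edv - sv_ml * eject
  refill <- 0.5 * (1 - cos(pi * (tb[!in_sys] - t_sys) / (t_beat - t_sys)))
  vol[!in_sys] <- esv_ml + sv_ml * refill
  structure(list(
    flow = data.frame(time_s = t, flow_ml_s = flow),
    lv_volume = data.frame(time_s = t, volume_ml = vol),
    hr_bpm = hr_bpm,
    beat_starts_s = seq(0, by = t_beat, length.out = n_beats + 1),
    sv_aorta_ml = sv_aorta, sv_lv_ml = sv_ml
  ), class = "flow_curve")
}
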