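#' Compartment map: the digital lung phantom ground truth
#'
#' A voxel grid of volume fractions for the four compartments the lung ECV
#' model distinguishes: MR-invisible volume (`f_air`: air in the aerated
#' lung, non-water solids in soft tissue), intracellular water (`f_ic`),
#' extravascular-extracellular water (`f_ev`), and blood plasma water
#' (`f_pl`). Fractions sum to one in every voxel. Masks identify the lungs,
#' the surrounding body tissue, and the blood pool; `hematocrit` is the
#' red-cell water share of blood, so the ECV of a blood region is exactly
#' `1 - hematocrit`.
#'
#' @param dim integer length-3 grid dimensions (voxels).
#' @param voxel_mm numeric length-3 voxel size in mm.
#' @param f_air,f_ic,f_ev,f_pl numeric arrays of `dim` with per-voxel
#'   volume fractions.
#' @param lung_mask,body_mask,blood_mask logical arrays of `dim`.
#' @param hematocrit hematocrit fraction in (0, 1).
#' @param ap_axis index (1-3) of the anteroposterior axis; posterior is the
#'   increasing-index direction.
#' @return An object of class `compartment_map`.
#' @export
compartment_map <- function(dim, voxel_mm, f_air, f_ic, f_ev, f_pl,
                            lung_mask, body_mask, blood_mask,
                            hematocrit, ap_axis = 2L) {
  dim <- as.integer(dim)
  obj <- structure(
    list(dim = dim, voxel_mm = as.numeric(voxel_mm),
         f_air = f_air, f_ic = f_ic, f_ev = f_ev, f_pl = f_pl,
         lung_mask = lung_mask, body_mask = body_mask,
         blood_mask = blood_mask,
         hematocrit = hematocrit, ap_axis = as.integer(ap_axis)),
    class = "compartment_map")
  validate_compartment_map(obj)
  obj
}

#' Validate a compartment map against its invariants
#'
#' Checks per-voxel sum-to-one (tolerance 1e-9), fraction bounds,
#' `f_air = 0` in the blood pool, and hematocrit in (0, 1).
#'
#' @param map a [compartment_map()].
#' @return `map`, invisibly; errors with a diagnostic on violation.
#' @export
validate_compartment_map <- function(map) {
  for (f in c("f_air", "f_ic", "f_ev", "f_pl")) {
    v <- map[[f]]
    if (!identical(dim(v), map$dim) && !identical(as.integer(dim(v)), map$dim))
      stop_lungecv(sprintf("%s has wrong dimensions", f))
    if (any(v < -1e-12 | v > 1 + 1e-12))
      stop_lungecv(sprintf("%s outside [0, 1]", f))
  }
  s <- map$f_air + map$f_ic + map$f_ev + map$f_pl
  bad <- abs(s - 1) > 1e-9
  if (any(bad))
    stop_lungecv(sprintf(
      "compartment fractions do not sum to 1 in %d voxel(s) (max |err| %.3g)",
      sum(bad), max(abs(s - 1))))
  if (any(map$f_air[map$blood_mask] != 0))
    stop_lungecv("f_air must be 0 in blood-pool voxels")
  if (!(map$hematocrit > 0 && map$hematocrit < 1))
    stop_lungecv("hematocrit must be in (0, 1)")
  invisible(map)
}

#' @export
print.compartment_map <- function(x, ...) {
  cat("compartment_map:", paste(x$dim, collapse = " x "), "voxels,",
      paste(x$voxel_mm, collapse = " x "), "mm\n")
  cat(sprintf("  lung %d, body %d, blood %d voxels; Hct %.2f; AP axis %d\n",
              sum(x$lung_mask), sum(x$body_mask), sum(x$blood_mask),
              x$hematocrit, x$ap_axis))
  w <- x$f_ic + x$f_ev + x$f_pl
  lm <- x$lung_mask
  cat(sprintf("  lung means: water %.3f, ECV %.3f, PVF %.3f\n",
              mean(w[lm]),
              mean(((x$f_ev + x$f_pl) / w)[lm]),
              mean((x$f_pl / w)[lm])))
  invisible(x)
}

#' Scene parameters for a phantom scenario
#'
#' Defaults emulate the porcine study arms: a naive control, a paired
#' baseline/mitral-regurgitation pair (regurgitation raises the
#' extravascular-extracellular fraction), and an intravascular volume-loaded
#' arm (raised plasma fraction, lowered hematocrit). Lung compartment
#' targets are expressed the way the study reports them: lung water density
#' (`lwd`, total water per voxel volume), ECV and plasma volume fraction
#' (both air-excluded), from which the voxel fractions follow as
#' `f_pl = pvf * lwd`, `f_ev = (ecv - pvf) * lwd`, `f_ic = (1 - ecv) * lwd`,
#' `f_air = 1 - lwd`.
#'
#' @param scenario one of `"naive"`, `"mr_baseline"`,
#'   `"mitral_regurgitation"`, `"volume_loaded"`.
#' @param lwd,ecv,pvf,hct lung-mean targets overriding the scenario default.
#' @param ap_gradient fractional change of the plasma fraction from the
#'   anterior to the posterior lung edge, relative to the lung mean
#'   (0 = uniform lung; positive = gravity-dependent pooling).
#' @param ev_gradient same convention for the extravascular-extracellular
#'   fraction; negative values put more interstitial water anteriorly, the
#'   pattern seen away from the gravity-dependent lung.
#' @param dim,voxel_mm phantom grid; the default voxel size is chosen so a
#'   small grid still carries a realistic lung volume.
#' @param lung_volume_l target total lung volume (L); when non-`NULL` the
#'   voxel size is rescaled isotropically so the lung mask carries exactly
#'   this volume. Per-arm defaults follow the study conditions.
#' @param sv_ml,hr_bpm,rf,ptt_s hemodynamic truth for the flow / first-pass
#'   simulators: total left-ventricular stroke volume (mL), heart rate,
#'   mitral regurgitant fraction, pulmonary transit time (s).
#' @return A named list of scene parameters.
#' @export
phantom_params <- function(scenario = c("naive", "mr_baseline",
                                        "mitral_regurgitation",
                                        "volume_loaded"),
                           lwd = NULL, ecv = NULL, pvf = NULL, hct = NULL,
                           ap_gradient = NULL, ev_gradient = NULL,
                           dim = c(32L, 32L, 6L), voxel_mm = c(7, 7, 10),
                           lung_volume_l = NULL,
                           sv_ml = NULL, hr_bpm = NULL, rf = NULL,
                           ptt_s = NULL) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    naive = list(lwd = 0.33, ecv = 0.644, pvf = 0.42, hct = 0.23,
                 ap_gradient = 0.15, ev_gradient = -0.3,
                 lung_volume_l = 0.93,
                 sv_ml = 42, hr_bpm = 83, rf = 0, ptt_s = 7.5),
    mr_baseline = list(lwd = 0.30, ecv = 0.70, pvf = 0.43, hct = 0.26,
                       ap_gradient = 0.15, ev_gradient = -0.3,
                       lung_volume_l = 1.33,
                       sv_ml = 46, hr_bpm = 109, rf = 0, ptt_s = 7.3),
    mitral_regurgitation = list(lwd = 0.31, ecv = 0.78, pvf = 0.46,
                                hct = 0.26, ap_gradient = 0.15,
                                ev_gradient = -0.5, lung_volume_l = 1.33,
                                sv_ml = 53, hr_bpm = 122, rf = 0.49,
                                ptt_s = 7.3),
    volume_loaded = list(lwd = 0.32, ecv = 0.73, pvf = 0.51, hct = 0.18,
                         ap_gradient = 0.20, ev_gradient = -0.1,
                         lung_volume_l = 1.23,
                         sv_ml = 55, hr_bpm = 95, rf = 0, ptt_s = 6.8))
  out <- list(scenario = scenario,
              lwd = lwd %||% defaults$lwd,
              ecv = ecv %||% defaults$ecv,
              pvf = pvf %||% defaults$pvf,
              hct = hct %||% defaults$hct,
              ap_gradient = ap_gradient %||% defaults$ap_gradient,
              ev_gradient = ev_gradient %||% defaults$ev_gradient,
              lung_volume_l = lung_volume_l %||% defaults$lung_volume_l,
              dim = as.integer(dim), voxel_mm = as.numeric(voxel_mm),
              sv_ml = sv_ml %||% defaults$sv_ml,
              hr_bpm = hr_bpm %||% defaults$hr_bpm,
              rf = rf %||% defaults$rf,
              ptt_s = ptt_s %||% defaults$ptt_s)
  out
}

# elliptical-cross-section geometry shared by all scenarios: body cylinder,
# two lungs, a central blood pool. Axis 1 = left-right, axis 2 = AP.
phantom_geometry <- function(dim) {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  x <- (seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  y <- (seq_len(ny) - (ny + 1) / 2) / (ny / 2)
  X <- array(rep(x, times = ny * nz), dim = dim)
  Y <- array(rep(rep(y, each = nx), times = nz), dim = dim)
  body <- (X / 0.95)^2 + (Y / 0.85)^2 <= 1
  lung_r <- ((X - 0.45) / 0.38)^2 + (Y / 0.55)^2 <= 1
  lung_l <- ((X + 0.45) / 0.38)^2 + (Y / 0.55)^2 <= 1
  lung <- (lung_r | lung_l) & body
  blood <- (X / 0.14)^2 + ((Y + 0.1) / 0.20)^2 <= 1 & body & !lung
  list(body = body & !lung & !blood, lung = lung, blood = blood)
}

#' Build a synthetic lung phantom with exported ground truth
#'
#' Constructs a [compartment_map()] for one study arm and derives its
#' [phantom_truth()]: the air-excluded ECV, plasma volume fraction and
#' extravascular ECV, lung water density and volumes, plus the hemodynamic
#' quantities the flow and first-pass simulators encode.
#'
#' @param scenario scenario label, see [phantom_params()].
#' @param params scene parameters from [phantom_params()]; defaults to the
#'   scenario's study conditions.
#' @param seed integer seed (reserved for randomized scene variants; the
#'   default geometry is deterministic).
#' @return list with elements `map` ([compartment_map()]), `truth`
#'   ([phantom_truth()]) and `params`.
#' @export
build_phantom <- function(scenario = c("naive", "mr_baseline",
                                       "mitral_regurgitation",
                                       "volume_loaded"),
                          params = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  params <- params %||% phantom_params(scenario)
  stopifnot(params$scenario == scenario)
  g <- phantom_geometry(params$dim)
  dm <- params$dim
  zero <- array(0, dim = dm)

  # rescale voxel size isotropically so the lung mask carries the target
  # lung volume of the arm (1 mL = 1000 mm^3)
  voxel_mm <- params$voxel_mm
  if (!is.null(params$lung_volume_l)) {
    have_ml <- sum(g$lung) * prod(voxel_mm) / 1000
    voxel_mm <- voxel_mm * (params$lung_volume_l * 1000 / have_ml)^(1 / 3)
    params$voxel_mm <- voxel_mm
  }

  # lung voxel fractions from the reported-quantity targets
  w <- params$lwd
  f_pl_mean <- params$pvf * w
  f_ev_mean <- (params$ecv - params$pvf) * w
  f_ic_mean <- (1 - params$ecv) * w
  if (min(f_pl_mean, f_ev_mean, f_ic_mean) < 0 || w <= 0 || w >= 1)
    stop_lungecv("scene targets imply negative compartment fractions")

  f_air <- zero; f_ic <- zero; f_ev <- zero; f_pl <- zero

  # anteroposterior plasma gradient over the lung bounding box
  idx_lung <- which(g$lung, arr.ind = TRUE)
  ap <- idx_lung[, params$ap_axis %||% 2L]
  ap_axis <- 2L
  rng <- range(ap)
  u <- if (diff(rng) > 0) (ap - rng[1]) / diff(rng) else rep(0.5, length(ap))
  f_pl_l <- f_pl_mean * (1 + params$ap_gradient * (u - 0.5))
  f_ev_l <- f_ev_mean * (1 + (params$ev_gradient %||% 0) * (u - 0.5))
  if (any(f_pl_l < 0) || any(f_ev_l < 0))
    stop_lungecv("AP gradients drive compartment fractions negative")
  f_ic[g$lung] <- f_ic_mean
  f_ev[g$lung] <- f_ev_l
  f_pl[g$lung] <- f_pl_l
  f_air_l <- 1 - f_ic_mean - f_ev_l - f_pl_l
  if (any(f_air_l < 0))
    stop_lungecv("AP gradients drive lung fractions above 1; reduce them")
  f_air[g$lung] <- f_air_l

  # body soft tissue: 70% water (musculoskeletal), remainder MR-invisible solids
  f_air[g$body] <- 0.30
  f_ic[g$body] <- 0.55
  f_ev[g$body] <- 0.15

  # blood pool: all water; hematocrit = red-cell water share
  hct <- params$hct
  f_ic[g$blood] <- hct
  f_pl[g$blood] <- 1 - hct

  # air outside the body
  outside <- !(g$body | g$lung | g$blood)
  f_air[outside] <- 1

  map <- compartment_map(dm, voxel_mm, f_air, f_ic, f_ev, f_pl,
                         lung_mask = g$lung, body_mask = g$body,
                         blood_mask = g$blood, hematocrit = hct,
                         ap_axis = ap_axis)
  truth <- phantom_truth(map, params)
  list(map = map, truth = truth, params = params)
}

#' Ground-truth summary of a phantom
#'
#' Computes the quantities the analysis pipeline is supposed to recover:
#' voxel-wise air-excluded compartment ratios averaged over the lung mask,
#' lung water density and volumes, and the hemodynamic parameters carried by
#' the scene.
#'
#' @param map a [compartment_map()].
#' @param params scene parameters ([phantom_params()]); hemodynamic truths
#'   are taken from here and may be `NULL`.
#' @return An object of class `phantom_truth` (named list).
#' @export
phantom_truth <- function(map, params = NULL) {
  lm <- map$lung_mask
  w <- (map$f_ic + map$f_ev + map$f_pl)[lm]
  ecv <- mean(((map$f_ev + map$f_pl)[lm]) / w)
  pvf <- mean((map$f_pl[lm]) / w)
  voxel_ml <- prod(map$voxel_mm) / 1000   # mm^3 -> mL (1 mL = 1000 mm^3)
  lung_volume_ml <- sum(lm) * voxel_ml
  lwd <- mean(w)
  lwv_ml <- lwd * lung_volume_ml
  sv <- params$sv_ml %||% NA_real_
  rf <- params$rf %||% NA_real_
  structure(list(
    ecv = ecv,
    pvf = pvf,
    ecv_ev = ecv - pvf,
    lung_water_density = lwd,
    lung_volume_l = lung_volume_ml / 1000,
    lung_water_volume_ml = lwv_ml,
    evlw_ml = (ecv - pvf) * lwv_ml,
    f_ev_total_ml = sum(map$f_ev[lm]) * voxel_ml,
    hematocrit = map$hematocrit,
    ptt_s = params$ptt_s %||% NA_real_,
    sv_lv_ml = sv,
    sv_aorta_ml = if (is.na(sv)) NA_real_ else sv * (1 - rf),
    regurgitant_fraction = rf,
    hr_bpm = params$hr_bpm %||% NA_real_
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "phantom truth: ECV %.1f%%, PVF %.1f%%, ECV_ev %.1f%%, LWD %.1f%%\n",
    100 * x$ecv, 100 * x$pvf, 100 * x$ecv_ev, 100 * x$lung_water_density))
  cat(sprintf("  lung %.2f L, LWV %.0f mL, EVLW %.0f mL, Hct %.2f\n",
              x$lung_volume_l, x$lung_water_volume_ml, x$evlw_ml,
              x$hematocrit))
  invisible(x)
}

#' Contrast phase description
#'
#' Plasma concentration and relaxivity of each agent at one imaging phase.
#' Gadolinium chelate equilibrates across the whole extracellular space
#' (plasma + extravascular-extracellular); ferumoxytol stays intravascular
#' and never contributes relaxation to the extravascular compartment.
#' `residual_gd` carries left-over gadolinium into a later phase (an
#' optional confounder; it clears with a 1.81 h half-life between phases
#' when simulated through [decay_residual_gd()]).
#'
#' @param label `"native"`, `"gadolinium"`, or `"ferumoxytol"`.
#' @param conc_gd,conc_fe plasma concentration (mmol/L) of gadolinium
#'   chelate and ferumoxytol.
#' @param r1_gd,r1_fe longitudinal relaxivities in L/mmol/s (converted to
#'   per-ms internally).
#' @param residual_gd gadolinium concentration (mmol/L) remaining from an
#'   earlier bolus, relaxing the extracellular space like `conc_gd`.
#' @return object of class `contrast_phase`.
#' @export
contrast_phase <- function(label = c("native", "gadolinium", "ferumoxytol"),
                           conc_gd = NULL, conc_fe = NULL,
                           r1_gd = 4.5, r1_fe = 15, residual_gd = 0) {
  label <- match.arg(label)
  conc_gd <- conc_gd %||% switch(label, gadolinium = 0.25, 0)
  conc_fe <- conc_fe %||% switch(label, ferumoxytol = 0.36, 0)
  if (any(c(conc_gd, conc_fe, r1_gd, r1_fe, residual_gd) < 0))
    stop_lungecv("concentrations and relaxivities must be nonnegative")
  structure(list(label = label, conc_gd = conc_gd, conc_fe = conc_fe,
                 r1_gd = r1_gd, r1_fe = r1_fe, residual_gd = residual_gd),
            class = "contrast_phase")
}

#' Residual gadolinium after a clearance interval
#'
#' Exponential clearance with the agent's 1.81 h terminal half-life.
#'
#' @param conc_gd concentration at injection equilibrium (mmol/L).
#' @param hours elapsed time.
#' @param half_life_h terminal half-life in hours.
#' @return remaining concentration (mmol/L).
#' @export
decay_residual_gd <- function(conc_gd, hours, half_life_h = 1.81) {
  conc_gd * 2^(-hours / half_life_h)
}
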