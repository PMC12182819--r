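# Study-level orchestration: simulate whole subjects, analyze them with the
# same code path whether they live in memory or on disk, and run the group
# statistics of the study design.

# default coil-shading field for the proton-density simulator: a mild,
# strictly positive degree-2 polynomial
default_shading <- function() {
  list(order = 2L,
       coef = c(1, 0.08, -0.06, 0.10, 0.04, -0.08, 0.06, 0.03, -0.04, -0.05))
}

.scenarios_for_model <- function(model) {
  switch(model,
    naive = c(naive = "naive"),
    mitral_regurgitation = c(baseline = "mr_baseline",
                             mitral_regurgitation = "mitral_regurgitation"),
    volume_loaded = c(volume_loaded = "volume_loaded"),
    stop_lungecv("unknown model: ", model))
}

#' Simulate one study subject
#'
#' Draws a subject from the population of an experimental arm (between-animal
#' variability on the compartment targets, hematocrit, lung volume, native
#' T1s and hemodynamics; additional within-subject variability between
#' paired conditions), builds the phantom(s), and forward-simulates every
#' acquisition the pipeline consumes: SASHA series at the native, gadolinium
#' and ferumoxytol phases, a native-phase proton-density volume with coil
#' shading, a flow + LV-volume curve, and (at the gadolinium phase of the
#' first condition) first-pass indicator-dilution curves.
#'
#' @param model `"naive"`, `"mitral_regurgitation"` (paired
#'   baseline/regurgitation) or `"volume_loaded"`.
#' @param id subject identifier.
#' @param seed integer seed driving all of this subject's randomness.
#' @param snr single-average SASHA SNR at the fully recovered lung signal
#'   (`Inf` = noiseless).
#' @param pd_noise Rician noise sigma of the proton-density volume relative
#'   to unit water signal.
#' @param shading shading field spec (see [simulate_proton_density()]);
#'   `NULL` disables shading.
#' @param biological_cv set to 0 to disable all between/within-subject
#'   variability (every subject is then the arm's mean animal); 1 keeps the
#'   calibrated defaults.
#' @param dim phantom grid dimensions.
#' @return a `lungecv_subject` list: `id`, `model`, `hematocrit`,
#'   `conditions` (each with `map`, `truth`, `series` per phase, `pd`,
#'   `flow`, optional `first_pass`), and `acquisition`.
#' @export
simulate_subject <- function(model = c("naive", "mitral_regurgitation",
                                       "volume_loaded"),
                             id = model, seed = 1L, snr = 30,
                             pd_noise = 0.01, shading = default_shading(),
                             biological_cv = 1, dim = c(32L, 32L, 6L)) {
  model <- match.arg(model)
  scen <- .scenarios_for_model(model)
  bc <- biological_cv
  with_seed(seed, {
    # between-animal offsets (shared by paired conditions)
    s_pvf <- stats::rnorm(1, 0, 0.08 * bc)
    s_evv <- stats::rnorm(1, 0, 0.12 * bc)
    s_lwd <- stats::rnorm(1, 0, 0.06 * bc)
    s_vol <- stats::rnorm(1, 0, 0.10 * bc)
    s_sv <- stats::rnorm(1, 0, 0.08 * bc)
    s_hr <- stats::rnorm(1, 0, 0.05 * bc)
    s_ptt <- stats::rnorm(1, 0, 0.08 * bc)
    hct0 <- phantom_params(scen[[1]])$hct
    hct <- min(max(hct0 + stats::rnorm(1, 0, 0.02 * bc), 0.08), 0.45)
    t1_lung <- stats::rnorm(1, 931, 45 * bc)
    t1_blood <- stats::rnorm(1, 1199, 60 * bc)

    conditions <- list()
    first <- TRUE
    for (cond in names(scen)) {
      p0 <- phantom_params(scen[[cond]])
      # within-subject (condition-level) variability
      c_pvf <- stats::rnorm(1, 0, 0.08 * bc)
      c_evv <- stats::rnorm(1, 0, 0.05 * bc)
      c_lwd <- stats::rnorm(1, 0, 0.03 * bc)
      pvf_t <- min(max(p0$pvf * (1 + s_pvf + c_pvf), 0.20), 0.65)
      evv_t <- min(max((p0$ecv - p0$pvf) * (1 + s_evv + c_evv), 0.05), 0.50)
      lwd_t <- min(max(p0$lwd * (1 + s_lwd + c_lwd), 0.15), 0.50)
      rf_t <- if (p0$rf > 0)
        min(max(p0$rf + stats::rnorm(1, 0, 0.05 * bc), 0.2), 0.8) else 0
      params <- phantom_params(
        scen[[cond]], lwd = lwd_t, ecv = pvf_t + evv_t, pvf = pvf_t,
        hct = hct, dim = dim,
        lung_volume_l = p0$lung_volume_l * (1 + s_vol),
        sv_ml = p0$sv_ml * (1 + s_sv), hr_bpm = p0$hr_bpm * (1 + s_hr),
        rf = rf_t, ptt_s = p0$ptt_s * (1 + s_ptt))
      ph <- build_phantom(scen[[cond]], params = params)

      series <- list()
      for (phase in c("native", "gadolinium", "ferumoxytol")) {
        t1v <- simulate_t1_volume(ph$map, contrast_phase(phase),
                                  native_r1_tissue = 1 / t1_lung,
                                  native_r1_blood = 1 / t1_blood)
        av <- ph$map$f_ic + ph$map$f_ev + ph$map$f_pl
        series[[phase]] <- simulate_sasha_series(
          t1v$t1, av, sasha_protocol(snr = snr),
          lung_mask = ph$map$lung_mask,
          seed = sample.int(.Machine$integer.max, 1))
      }
      pd <- simulate_proton_density(ph$map, shading = shading,
                                    noise_sd = pd_noise,
                                    seed = sample.int(.Machine$integer.max, 1))
      flow <- simulate_flow(params$sv_ml, params$hr_bpm, rf = params$rf,
                            noise_sd = 0.02 * params$sv_ml,
                            seed = sample.int(.Machine$integer.max, 1))
      fp <- NULL
      if (first) {
        fp <- simulate_first_pass(params$ptt_s, cnr = 15,
                                  seed = sample.int(.Machine$integer.max, 1))
        first <- FALSE
      }
      conditions[[cond]] <- list(scenario = scen[[cond]], params = params,
                                 map = ph$map, truth = ph$truth,
                                 series = series, pd = pd, flow = flow,
                                 first_pass = fp)
    }
    structure(list(id = id, model = model, hematocrit = hct,
                   native_t1 = c(lung = t1_lung, blood = t1_blood),
                   conditions = conditions,
                   acquisition = sasha_protocol(snr = snr)),
              class = "lungecv_subject")
  })
}

# core per-condition analysis shared by the in-memory and on-disk routes.
# `cond` carries: series (list of sasha_series), pd array, masks, voxel_mm,
# hematocrit, flow pieces, first_pass.
.analyze_condition <- function(cond, hematocrit, condition_label,
                               regional = TRUE, ap_axis = 2L,
                               fit_model = "3param") {
  fit_mask <- cond$lung_mask | cond$blood_mask
  maps <- lapply(cond$series, fit_t1, mask = fit_mask, model = fit_model)
  t1 <- list(
    lung_native = roi_t1(maps$native, cond$lung_mask),
    lung_gd = roi_t1(maps$gadolinium, cond$lung_mask),
    lung_fe = roi_t1(maps$ferumoxytol, cond$lung_mask),
    blood_native = roi_t1(maps$native, cond$blood_mask),
    blood_gd = roi_t1(maps$gadolinium, cond$blood_mask),
    blood_fe = roi_t1(maps$ferumoxytol, cond$blood_mask))
  res <- ecv_result(t1, hematocrit, condition = condition_label)

  regional_res <- NULL
  if (regional) {
    secs <- regional_sections(cond$lung_mask, ap_axis = ap_axis)
    regional_res <- lapply(secs, function(m) {
      tt <- list(lung_native = roi_t1(maps$native, m),
                 lung_gd = roi_t1(maps$gadolinium, m),
                 lung_fe = roi_t1(maps$ferumoxytol, m),
                 blood_native = t1$blood_native,
                 blood_gd = t1$blood_gd,
                 blood_fe = t1$blood_fe)
      ecv_result(tt, hematocrit, condition = condition_label)
    })
  }

  body_ref <- body_reference_mask(cond$body_mask, cond$lung_mask, ring = 2L)
  sc <- shading_correction(cond$pd, body_ref, order = 2L)
  lwd <- lung_water_density(sc$corrected, cond$lung_mask, body_ref)
  lung_volume_l <- sum(cond$lung_mask) * prod(cond$voxel_mm) / 1e6
  lwv <- lung_water_volume(lwd$global, lung_volume_l)
  evlw <- extravascular_lung_water_volume(max(res$ecv_ev, 0), lwv)

  sv_aorta <- co <- sv_lv <- rf <- ptt <- pbv <- NA_real_
  if (!is.null(cond$flow)) {
    sv_aorta <- stroke_volume(cond$flow)
    co <- cardiac_output(sv_aorta, cond$flow$hr_bpm)
    if (!is.null(cond$flow$lv_volume)) {
      sv_lv <- lv_stroke_volume(cond$flow$lv_volume)
      rf <- as.numeric(regurgitant_fraction(sv_lv, sv_aorta))
    }
  }
  if (!is.null(cond$first_pass)) {
    ptt <- pulmonary_transit_time(cond$first_pass)
    if (is.finite(co)) pbv <- pulmonary_blood_volume(ptt, co)
  }

  row <- data.frame(
    condition = condition_label,
    ecv = res$ecv, pvf = res$pvf, ecv_ev = res$ecv_ev,
    t1_lung_native = t1$lung_native, t1_lung_gd = t1$lung_gd,
    t1_lung_fe = t1$lung_fe, t1_blood_native = t1$blood_native,
    t1_blood_gd = t1$blood_gd, t1_blood_fe = t1$blood_fe,
    dr1_lung_gd = res$dr1$lung_gd, dr1_lung_fe = res$dr1$lung_fe,
    lwd = lwd$global, lung_volume_l = lung_volume_l,
    lwv_ml = lwv, evlw_ml = evlw,
    sv_aorta_ml = sv_aorta, sv_lv_ml = sv_lv, co_l_min = co, rf = rf,
    ptt_s = ptt, pbv_ml = pbv,
    flagged = res$flagged, stringsAsFactors = FALSE)
  if (regional) {
    for (sec in names(regional_res)) {
      row[[paste0("ecv_", sec)]] <- regional_res[[sec]]$ecv
      row[[paste0("pvf_", sec)]] <- regional_res[[sec]]$pvf
      row[[paste0("ecv_ev_", sec)]] <- regional_res[[sec]]$ecv_ev
    }
  }
  list(row = row, ecv_result = res, regional = regional_res, t1 = t1,
       lwd = lwd)
}

#' Analyze one subject
#'
#' Runs the full measurement chain on a simulated (or loaded) subject:
#' voxel-wise SASHA T1 fits, ROI means, phase pairing, dual-agent ECV /
#' plasma volume fraction / extravascular ECV (globally and in
#' anteroposterior thirds), shading-corrected lung water density and
#' volumes, extravascular lung water volume, and flow / first-pass
#' hemodynamics.
#'
#' @param subject a [simulate_subject()] object.
#' @param regional compute the anteroposterior regional breakdown.
#' @param fit_model T1 model passed to [fit_t1()].
#' @return list with `table` (one data-frame row per condition) and
#'   `details` (per-condition [ecv_result()]s and diagnostics).
#' @export
analyze_subject <- function(subject, regional = TRUE, fit_model = "3param") {
  stopifnot(inherits(subject, "lungecv_subject"))
  rows <- list(); details <- list()
  for (cond in names(subject$conditions)) {
    cd <- subject$conditions[[cond]]
    payload <- list(series = cd$series, pd = cd$pd$pd,
                    lung_mask = cd$map$lung_mask,
                    body_mask = cd$map$body_mask,
                    blood_mask = cd$map$blood_mask,
                    voxel_mm = cd$map$voxel_mm,
                    flow = cd$flow, first_pass = cd$first_pass)
    out <- .analyze_condition(payload, subject$hematocrit, cond,
                              regional = regional,
                              ap_axis = cd$map$ap_axis,
                              fit_model = fit_model)
    out$row <- cbind(data.frame(subject = subject$id, model = subject$model,
                                stringsAsFactors = FALSE), out$row)
    rows[[cond]] <- out$row
    details[[cond]] <- out[c("ecv_result", "regional", "t1", "lwd")]
  }
  list(table = do.call(rbind, rows), details = details)
}

#' Simulate and analyze a full study
#'
#' Generates the study cohorts (by default n = 5 subjects in each of the
#' naive, mitral-regurgitation and volume-loaded arms), analyzes every
#' subject, and collects per-condition results and ground truths.
#'
#' @param arms named integer vector: subjects per model.
#' @param seed master seed; subject seeds are drawn from it.
#' @param ... passed to [simulate_subject()] (e.g. `snr`, `dim`,
#'   `biological_cv`).
#' @return list with `results` (data frame, one row per subject-condition),
#'   `truth` (same shape, simulated ground truths), `subject_seeds`.
#' @export
run_study <- function(arms = c(naive = 5L, mitral_regurgitation = 5L,
                               volume_loaded = 5L),
                      seed = 1L, ...) {
  seeds <- with_seed(seed, sample.int(2^30, sum(arms)))
  res <- list(); tru <- list(); k <- 0L
  for (model in names(arms)) {
    for (i in seq_len(arms[[model]])) {
      k <- k + 1L
      id <- sprintf("%s_%02d", model, i)
      sub <- simulate_subject(model, id = id, seed = seeds[k], ...)
      an <- analyze_subject(sub)
      res[[id]] <- an$table
      tru[[id]] <- do.call(rbind, lapply(names(sub$conditions), function(cn) {
        tr <- sub$conditions[[cn]]$truth
        data.frame(subject = id, model = model, condition = cn,
                   ecv = tr$ecv, pvf = tr$pvf, ecv_ev = tr$ecv_ev,
                   lwd = tr$lung_water_density,
                   lung_volume_l = tr$lung_volume_l,
                   lwv_ml = tr$lung_water_volume_ml,
                   evlw_ml = tr$evlw_ml, ptt_s = tr$ptt_s,
                   sv_lv_ml = tr$sv_lv_ml, sv_aorta_ml = tr$sv_aorta_ml,
                   rf = tr$regurgitant_fraction,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  list(results = do.call(rbind, res), truth = do.call(rbind, tru),
       subject_seeds = seeds)
}

#' Group statistics of the study design
#'
#' Paired t-tests for baseline vs mitral regurgitation, unpaired t-tests for
#' naive vs volume-loaded, and the regional repeated-measures ANOVA with
#' Greenhouse-Geisser correction (naive and mitral-regurgitation baseline
#' grouped as the no-intervention cohort, per the study design; the grouping
#' is an argument, not hard-coded).
#'
#' @param results the `results` data frame from [run_study()] (or
#'   [run_pipeline()]).
#' @param measures columns to compare.
#' @param no_intervention condition labels pooled for the regional analysis.
#' @return nested list of test results.
#' @export
study_statistics <- function(results,
                             measures = c("ecv", "pvf", "ecv_ev", "evlw_ml"),
                             no_intervention = c("naive", "baseline")) {
  out <- list()
  base <- results[results$condition == "baseline", ]
  mr <- results[results$condition == "mitral_regurgitation", ]
  if (nrow(base) >= 2 && nrow(mr) >= 2) {
    ord <- match(base$subject, mr$subject)
    mr <- mr[ord, ]
    out$paired_mr <- lapply(stats::setNames(measures, measures), function(m)
      paired_t(mr[[m]], base[[m]],
               ids = list(a = mr$subject, b = base$subject)))
  }
  nai <- results[results$condition == "naive", ]
  vol <- results[results$condition == "volume_loaded", ]
  if (nrow(nai) >= 2 && nrow(vol) >= 2) {
    out$unpaired_volume <- lapply(stats::setNames(measures, measures),
                                  function(m) unpaired_t(vol[[m]], nai[[m]]))
  }
  reg_cols <- paste0("pvf_", c("anterior", "mid", "posterior"))
  if (all(reg_cols %in% names(results))) {
    grp <- results[results$condition %in% no_intervention, ]
    if (nrow(grp) >= 3) {
      out$regional <- list(
        pvf = rm_anova_gg(as.matrix(grp[, reg_cols])),
        ecv_ev = rm_anova_gg(as.matrix(
          grp[, paste0("ecv_ev_", c("anterior", "mid", "posterior"))])))
    }
  }
  out
}
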