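# Writing a simulated study to disk and running the pipeline from a
# manifest. The on-disk layout is NIfTI volumes + CSV time-series + a YAML
# manifest, so the analysis route is identical for simulated and acquired
# data.

#' Write a simulated study to disk
#'
#' Lays out one directory per subject containing masks, 4D saturation-
#' recovery series per phase, native-phase proton-density volumes, flow and
#' LV-volume CSVs, first-pass CSVs, and a `truth.json` per subject; writes a
#' `manifest.yaml` at the root binding everything together.
#'
#' @param subjects list of [simulate_subject()] objects (a single subject is
#'   accepted too).
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(subjects, dir) {
  if (inherits(subjects, "lungecv_subject")) subjects <- list(subjects)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man_subjects <- list()
  for (sub in subjects) {
    sdir <- file.path(dir, sub$id)
    dir.create(sdir, showWarnings = FALSE)
    cond1 <- sub$conditions[[1]]
    vm <- cond1$map$voxel_mm
    rel <- function(...) file.path(sub$id, ...)
    write_volume(cond1$map$lung_mask, file.path(sdir, "mask_lung.nii.gz"), vm)
    write_volume(cond1$map$body_mask, file.path(sdir, "mask_body.nii.gz"), vm)
    write_volume(cond1$map$blood_mask, file.path(sdir, "mask_blood.nii.gz"), vm)
    vols <- list(); flows <- list(); fps <- list(); truths <- list()
    ord <- 0L
    for (cn in names(sub$conditions)) {
      cd <- sub$conditions[[cn]]
      for (phase in c("native", "gadolinium", "ferumoxytol")) {
        ord <- ord + 1L
        ser <- cd$series[[phase]]
        f <- sprintf("series_%s_%s.nii.gz", phase, cn)
        write_volume(ser$frames, file.path(sdir, f), cd$map$voxel_mm)
        entry <- list(phase = phase, condition = cn, order = ord,
                      series = rel(f), ts_ms = ser$ts_ms,
                      averages = ser$averages, noise_sd = ser$noise_sd)
        if (phase == "native") {
          pf <- sprintf("pd_%s.nii.gz", cn)
          write_volume(cd$pd$pd, file.path(sdir, pf), cd$map$voxel_mm)
          entry$pd <- rel(pf)
          # each condition may carry its own voxel scale (lung volume)
          entry$voxel_mm <- cd$map$voxel_mm
        }
        vols[[length(vols) + 1L]] <- entry
      }
      ff <- sprintf("flow_%s.csv", cn)
      utils::write.csv(cd$flow$flow, file.path(sdir, ff), row.names = FALSE)
      lf <- sprintf("lv_volume_%s.csv", cn)
      utils::write.csv(cd$flow$lv_volume, file.path(sdir, lf),
                       row.names = FALSE)
      flows[[length(flows) + 1L]] <- list(
        condition = cn, flow = rel(ff), lv_volume = rel(lf),
        hr_bpm = cd$flow$hr_bpm)
      if (!is.null(cd$first_pass)) {
        pf <- sprintf("first_pass_%s.csv", cn)
        utils::write.csv(as.data.frame(cd$first_pass),
                         file.path(sdir, pf), row.names = FALSE)
        fps[[length(fps) + 1L]] <- list(
          condition = cn, path = rel(pf),
          frame_s = attr(cd$first_pass, "frame_s"))
      }
      truths[[cn]] <- unclass(cd$truth)
    }
    jsonlite::write_json(truths, file.path(sdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    man_subjects[[length(man_subjects) + 1L]] <- list(
      id = sub$id, model = sub$model, hematocrit = sub$hematocrit,
      ap_axis = cond1$map$ap_axis,
      masks = list(lung = rel("mask_lung.nii.gz"),
                   body = rel("mask_body.nii.gz"),
                   blood = rel("mask_blood.nii.gz")),
      volumes = vols, flow = flows, first_pass = fps)
  }
  manifest <- list(study = "lungecv-phantom-study",
                   subjects = man_subjects)
  path <- file.path(dir, "manifest.yaml")
  write_manifest(manifest, path)
  invisible(path)
}

#' Run the analysis pipeline from a study manifest
#'
#' Reads every subject's volumes and time-series from disk, fits T1 maps,
#' pairs phases per condition, and computes the full results bundle: global
#' and regional ECV / plasma volume fraction / extravascular ECV, lung water
#' density and volumes, hemodynamics, and the study's group statistics.
#' Deterministic given the manifest contents. Stage errors are rethrown with
#' the stage name and subject id.
#'
#' @param manifest path to a manifest file, or a directory containing
#'   `manifest.yaml`.
#' @param regional compute anteroposterior thirds.
#' @param fit_model T1 model (see [fit_t1()]).
#' @return list with `results` (data frame), `statistics`
#'   ([study_statistics()] output when the design allows), and `details`.
#' @export
run_pipeline <- function(manifest, regional = TRUE, fit_model = "3param") {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.yaml")
  dir <- dirname(manifest)
  man <- read_manifest(manifest)
  validate_manifest(man, dir = dir)
  pairs <- pair_phases(man)   # validates native/contrast completeness
  rows <- list(); details <- list()
  for (sub in man$subjects) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop_lungecv(sprintf("[%s] subject %s: %s", what, sub$id,
                             conditionMessage(e))))
    }
    lung <- stage("masks", read_volume(file.path(dir, sub$masks$lung)))
    body <- stage("masks", read_volume(file.path(dir, sub$masks$body)))
    blood <- stage("masks", read_volume(file.path(dir, sub$masks$blood)))
    check_same_grid(lung, body, "masks")
    check_same_grid(lung, blood, "masks")
    conds <- unique(vapply(sub$volumes, function(v) v$condition, character(1)))
    for (cn in conds) {
      ventry <- function(phase) {
        hit <- Filter(function(v) v$phase == phase && v$condition == cn,
                      sub$volumes)
        if (length(hit) == 0L)
          stop_lungecv(sprintf("subject %s: missing %s map for '%s'",
                               sub$id, phase, cn))
        hit[[1]]
      }
      series <- stage("t1-series", {
        lapply(stats::setNames(c("native", "gadolinium", "ferumoxytol"),
                               c("native", "gadolinium", "ferumoxytol")),
               function(phase) {
                 v <- ventry(phase)
                 vol <- read_volume(file.path(dir, v$series))
                 if (!identical(dim(vol$data)[1:3], dim(lung$data)))
                   stop_lungecv("series grid does not match masks")
                 list(frames = vol$data,
                      ts_ms = as.numeric(unlist(v$ts_ms)),
                      averages = as.numeric(unlist(v$averages)),
                      noise_sd = v$noise_sd %||% 0)
               })
      })
      nat <- ventry("native")
      pd <- stage("proton-density",
                  read_volume(file.path(dir, nat$pd)))
      voxel_mm <- as.numeric(unlist(nat$voxel_mm %||% lung$voxel_mm))
      fentry <- Filter(function(f) f$condition == cn, sub$flow)
      flow <- NULL
      if (length(fentry)) {
        f <- fentry[[1]]
        flow <- list(
          flow = utils::read.csv(file.path(dir, f$flow)),
          lv_volume = if (!is.null(f$lv_volume))
            utils::read.csv(file.path(dir, f$lv_volume)) else NULL,
          hr_bpm = f$hr_bpm, beat_starts_s = NULL)
        class(flow) <- "flow_curve"
      }
      pentry <- Filter(function(f) f$condition == cn, sub$first_pass %||% list())
      fp <- if (length(pentry))
        utils::read.csv(file.path(dir, pentry[[1]]$path)) else NULL
      payload <- list(series = series, pd = pd$data,
                      lung_mask = lung$data > 0.5,
                      body_mask = body$data > 0.5,
                      blood_mask = blood$data > 0.5,
                      voxel_mm = voxel_mm, flow = flow, first_pass = fp)
      out <- stage(paste0("analysis:", cn),
                   .analyze_condition(payload, sub$hematocrit, cn,
                                      regional = regional,
                                      ap_axis = sub$ap_axis %||% 2L,
                                      fit_model = fit_model))
      out$row <- cbind(data.frame(subject = sub$id, model = sub$model,
                                  stringsAsFactors = FALSE), out$row)
      rows[[paste(sub$id, cn)]] <- out$row
      details[[paste(sub$id, cn)]] <- out[c("ecv_result", "regional", "t1")]
    }
  }
  results <- do.call(rbind, rows)
  stats_out <- tryCatch(study_statistics(results), error = function(e) NULL)
  list(results = results, statistics = stats_out, details = details,
       pairs = pairs)
}
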