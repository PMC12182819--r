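# Dual-contrast compartment analysis.
#
# ECV = (1 - hematocrit) * dR1_lung / dR1_blood with an extracellular
# (gadolinium) agent; the same formula with a purely intravascular agent
# (ferumoxytol) yields the blood plasma volume fraction; their difference is
# the extravascular (interstitial) ECV. All fractions are air-excluded:
# they describe shares of the non-air voxel water, not of the voxel volume.

#' Extracellular volume fraction from paired delta-R1
#'
#' `ECV = (1 - hematocrit) * dR1_lung / dR1_blood`. A negative delta-R1
#' (post-contrast T1 longer than native) yields a flagged result with a
#' warning rather than an error; a blood delta-R1 indistinguishable from
#' zero is an error because the contrast change is uninterpretable.
#'
#' @param dr1_lung,dr1_blood relaxation-rate changes (1/ms), e.g. from
#'   [delta_r1()].
#' @param hematocrit hematocrit fraction in (0, 1).
#' @param tol threshold below which `|dr1_blood|` counts as zero.
#' @return ECV fraction (numeric scalar). Results outside the soft
#'   physiological window [0, 1.2] or built from negative delta-R1 carry a
#'   `flagged` attribute (and a warning); values are never clipped.
#' @export
compute_ecv <- function(dr1_lung, dr1_blood, hematocrit, tol = 1e-9) {
  if (!(hematocrit > 0 && hematocrit < 1))
    stop_lungecv("hematocrit must be in (0, 1)")
  dr1_lung <- as.numeric(dr1_lung)
  dr1_blood <- as.numeric(dr1_blood)
  if (abs(dr1_blood) < tol)
    stop_lungecv("blood delta-R1 is zero within tolerance; contrast change uninterpretable")
  ecv <- (1 - hematocrit) * (dr1_lung / dr1_blood)
  flagged <- dr1_lung < 0 || dr1_blood < 0 || ecv < 0 || ecv > 1.2
  if (flagged) {
    warning("ECV flagged: negative delta-R1 or value outside [0, 1.2]",
            call. = FALSE)
    attr(ecv, "flagged") <- TRUE
  }
  ecv
}

#' Blood plasma volume fraction from ferumoxytol delta-R1
#'
#' Identical contract to [compute_ecv()], with both delta-R1 values measured
#' for the intravascular agent against the native (pre-gadolinium) R1.
#'
#' @inheritParams compute_ecv
#' @return plasma volume fraction (numeric scalar), flagged as in
#'   [compute_ecv()].
#' @export
compute_pvf <- function(dr1_lung, dr1_blood, hematocrit, tol = 1e-9) {
  compute_ecv(dr1_lung, dr1_blood, hematocrit, tol = tol)
}

#' Extravascular ECV
#'
#' `ECV_extravascular = ECV - plasma volume fraction`. Negative results are
#' physiologically impossible but statistically informative, so they are
#' flagged with a warning, never truncated.
#'
#' @param ecv,pvf fractions from [compute_ecv()] and [compute_pvf()].
#' @return extravascular ECV fraction.
#' @export
compute_ecv_extravascular <- function(ecv, pvf) {
  if (!is.finite(ecv) || !is.finite(pvf))
    stop_lungecv("ecv and pvf must be finite")
  out <- as.numeric(ecv) - as.numeric(pvf)
  if (out < 0) {
    warning("negative extravascular ECV flagged (not truncated)",
            call. = FALSE)
    attr(out, "flagged") <- TRUE
  }
  out
}

#' Assemble a full dual-agent ECV result
#'
#' Bundles the hematocrit, the four delta-R1 values, ECV, plasma volume
#' fraction and their difference for one subject/condition. The subtraction
#' identity `ecv_ev = ecv - pvf` holds exactly by construction.
#'
#' @param t1 named list of ROI T1 values (ms): `lung_native`, `lung_gd`,
#'   `lung_fe`, `blood_native`, `blood_gd`, `blood_fe`.
#' @param hematocrit hematocrit fraction.
#' @param condition label (`"naive"`, `"baseline"`, `"mitral_regurgitation"`,
#'   `"volume_loaded"`, ...).
#' @return object of class `ecv_result`.
#' @export
ecv_result <- function(t1, hematocrit, condition = "naive") {
  need <- c("lung_native", "lung_gd", "lung_fe", "blood_native",
            "blood_gd", "blood_fe")
  miss <- setdiff(need, names(t1))
  if (length(miss))
    stop_lungecv("missing T1 values: ", paste(miss, collapse = ", "))
  dr1_lung_gd <- delta_r1(t1$lung_gd, t1$lung_native)
  dr1_blood_gd <- delta_r1(t1$blood_gd, t1$blood_native)
  dr1_lung_fe <- delta_r1(t1$lung_fe, t1$lung_native)
  dr1_blood_fe <- delta_r1(t1$blood_fe, t1$blood_native)
  ecv <- compute_ecv(dr1_lung_gd, dr1_blood_gd, hematocrit)
  pvf <- compute_pvf(dr1_lung_fe, dr1_blood_fe, hematocrit)
  ecv_ev <- compute_ecv_extravascular(ecv, pvf)
  structure(list(
    condition = condition, hematocrit = hematocrit,
    dr1 = list(lung_gd = as.numeric(dr1_lung_gd),
               blood_gd = as.numeric(dr1_blood_gd),
               lung_fe = as.numeric(dr1_lung_fe),
               blood_fe = as.numeric(dr1_blood_fe)),
    t1 = t1,
    ecv = as.numeric(ecv), pvf = as.numeric(pvf),
    ecv_ev = as.numeric(ecv_ev),
    flagged = isTRUE(attr(ecv, "flagged")) || isTRUE(attr(pvf, "flagged")) ||
      isTRUE(attr(ecv_ev, "flagged"))
  ), class = "ecv_result")
}

#' @export
print.ecv_result <- function(x, ...) {
  cat(sprintf("ecv_result [%s]: ECV %.1f%%, PVF %.1f%%, ECV_ev %.1f%% (Hct %.2f)%s\n",
              x$condition, 100 * x$ecv, 100 * x$pvf, 100 * x$ecv_ev,
              x$hematocrit, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Pair native and post-contrast T1 maps by study phase
#'
#' Implements the study's pairing rules: in the mitral-regurgitation model,
#' baseline ECV uses baseline native + baseline contrast maps and
#' regurgitation ECV uses the regurgitation pair; the volume-loaded model
#' uses the post-infusion native; naive animals use their single native. A
#' naive subject whose ferumoxytol phase precedes the gadolinium phase is
#' still paired but labelled order-variant.
#'
#' @param manifest a study manifest list (see [read_manifest()]): each
#'   subject has `id`, `model`, `hematocrit`, and a list `volumes` of
#'   entries with `phase` (`native`/`gadolinium`/`ferumoxytol`),
#'   `condition`, and an `order` index.
#' @return data frame with one row per (subject, agent, condition):
#'   `subject`, `agent`, `condition`, `native_key`, `contrast_key`,
#'   `order_variant`.
#' @export
pair_phases <- function(manifest) {
  rows <- list()
  for (sub in manifest$subjects) {
    vols <- sub$volumes
    key <- function(phase, condition) {
      hit <- which(vapply(vols, function(v)
        v$phase == phase && v$condition == condition, logical(1)))
      if (length(hit) == 0L) return(NA_integer_)
      hit[1]
    }
    conds <- unique(vapply(vols, function(v) v$condition, character(1)))
    for (cond in conds) {
      nat <- key("native", cond)
      if (is.na(nat))
        stop_lungecv(sprintf(
          "subject %s: missing native map for condition '%s'", sub$id, cond))
      for (agent in c("gadolinium", "ferumoxytol")) {
        con <- key(agent, cond)
        if (is.na(con)) {
          stop_lungecv(sprintf(
            "subject %s: missing %s map for condition '%s'",
            sub$id, agent, cond))
        }
        ord <- function(i) vols[[i]]$order %||% i
        fe <- key("ferumoxytol", cond)
        gd <- key("gadolinium", cond)
        order_variant <- !is.na(fe) && !is.na(gd) && ord(fe) < ord(gd)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sub$id, agent = agent, condition = cond,
          native_key = nat, contrast_key = con,
          order_variant = order_variant, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Split a lung mask into anteroposterior thirds
#'
#' The bounding-box extent of the lung mask along the anteroposterior axis
#' is partitioned into three equal sections (anterior, mid, posterior);
#' remainder voxels from a non-divisible extent go to the posterior-most
#' eligible sections. Each returned sub-mask is the intersection of the
#' lung mask with its section.
#'
#' @param lung_mask logical 3D array.
#' @param ap_axis index of the anteroposterior axis (posterior = increasing
#'   index).
#' @return named list `anterior`, `mid`, `posterior` of logical arrays, with
#'   attribute `bounds` (the index ranges).
#' @export
regional_sections <- function(lung_mask, ap_axis = 2L) {
  if (sum(lung_mask) == 0L) stop_lungecv("empty lung mask")
  idx <- which(lung_mask, arr.ind = TRUE)
  ap <- idx[, ap_axis]
  rng <- range(ap)
  n <- diff(rng) + 1L
  if (n < 3L) stop_lungecv("lung extent along the AP axis is below 3 voxels")
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- base + c(0L, 0L, 0L)
  if (r >= 1L) sizes[3] <- sizes[3] + 1L
  if (r == 2L) sizes[2] <- sizes[2] + 1L
  ends <- rng[1] - 1L + cumsum(sizes)
  starts <- c(rng[1], ends[1] + 1L, ends[2] + 1L)
  out <- lapply(1:3, function(i) {
    m <- lung_mask
    keep <- slice.index(lung_mask, ap_axis) >= starts[i] &
      slice.index(lung_mask, ap_axis) <= ends[i]
    m & keep
  })
  names(out) <- c("anterior", "mid", "posterior")
  attr(out, "bounds") <- data.frame(section = names(out),
                                    start = starts, end = ends)
  out
}
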