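# Lung water density and volume from proton-density imaging.

#' Polynomial design basis over a voxel grid
#'
#' Monomials `x^i y^j z^k` with total degree `<= order` in coordinates
#' normalized to [-1, 1], evaluated at every voxel. Used by the shading
#' model on both the forward (simulation) and inverse (correction) side.
#'
#' @param dim grid dimensions.
#' @param order maximum total degree (0 = constant only).
#' @return matrix with `prod(dim)` rows, one column per monomial.
#' @export
poly_basis <- function(dim, order = 2L) {
  coord <- function(n, along) {
    u <- if (n > 1) seq(-1, 1, length.out = n) else 0
    a <- array(0, dim = dim)
    idx <- slice.index(a, along)
    u[idx]
  }
  X <- coord(dim[1], 1); Y <- coord(dim[2], 2); Z <- coord(dim[3], 3)
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j))
    cols[[length(cols) + 1L]] <- as.vector(X^i * Y^j * Z^k)
  do.call(cbind, cols)
}

#' Signal-intensity-based coil shading correction
#'
#' Fits a low-order polynomial field to the signal inside the body mask by
#' least squares, normalizes the field to unit mean over the body, and
#' divides it out of the whole volume. Body soft tissue is assumed
#' homogeneous, so its low-frequency intensity structure is attributed to
#' coil sensitivity.
#'
#' @param pd_volume proton-density signal array.
#' @param body_mask logical array of reference body tissue.
#' @param order polynomial total degree (default 2).
#' @return list with `corrected` (array), `field` (normalized shading
#'   field), `coef`, and `order`.
#' @export
shading_correction <- function(pd_volume, body_mask, order = 2L) {
  if (sum(body_mask) == 0L) stop_lungecv("empty body mask")
  X <- poly_basis(dim(pd_volume), order)
  Xb <- X[as.vector(body_mask), , drop = FALSE]
  if (qr(Xb)$rank < ncol(Xb))
    stop_lungecv("degenerate shading fit: body mask does not support a degree-",
                 order, " polynomial")
  coef <- qr.coef(qr(Xb), pd_volume[body_mask])
  field <- array(as.vector(X %*% coef), dim = dim(pd_volume))
  if (any(field[body_mask] <= 0))
    stop_lungecv("fitted shading field is nonpositive inside the body mask")
  scale <- mean(field[body_mask])
  field <- field / scale
  field[field <= 0] <- NA_real_      # outside-body extrapolation may vanish
  corrected <- pd_volume / field
  corrected[!is.finite(corrected)] <- 0
  list(corrected = corrected, field = field, coef = coef, order = order)
}

#' Reference body tissue mask for density normalization
#'
#' "Surrounding body tissue" for the lung water normalization: the body mask
#' minus the lungs, minus a dilation ring around the lungs to avoid
#' partial-volume contamination at the lung boundary.
#'
#' @param body_mask,lung_mask logical arrays.
#' @param ring dilation radius (voxels, chebyshev) removed around the lungs.
#' @return logical array.
#' @export
body_reference_mask <- function(body_mask, lung_mask, ring = 2L) {
  dil <- lung_mask
  if (ring > 0) {
    for (r in seq_len(ring)) {
      grown <- dil
      for (ax in 1:3)
        grown <- grown | abind_shift(dil, ax, 1L) | abind_shift(dil, ax, -1L)
      dil <- grown
    }
  }
  body_mask & !dil
}

# shift a logical array by `by` voxels along axis `ax`, padding with FALSE
abind_shift <- function(x, ax, by) {
  dm <- dim(x)
  out <- array(FALSE, dm)
  n <- dm[ax]
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  idx_src <- rep(list(quote(expr = )), 3); idx_dst <- idx_src
  idx_src[[ax]] <- src; idx_dst[[ax]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(do.call(`[`, c(list(x), idx_src,
                                              list(drop = FALSE))))))
  out
}

#' Lung water density map and global density
#'
#' Per-voxel lung water density is the ratio of the (shading-corrected)
#' pulmonary signal to the median signal in the surrounding body tissue,
#' scaled by the assumed 70% musculoskeletal water density. Densities above
#' 1.2 are flagged, never clipped. The lung mask is expected to already
#' exclude major vasculature (mask contract).
#'
#' @param corrected shading-corrected signal array.
#' @param lung_mask,body_mask disjoint, nonempty logical arrays; pass the
#'   output of [body_reference_mask()] as `body_mask`.
#' @param body_water assumed body tissue water density.
#' @return object of class `lwd_map`: `lwd` array (`NA` outside the lungs),
#'   `global` density (fraction), `body_median`, `n_flagged`.
#' @export
lung_water_density <- function(corrected, lung_mask, body_mask,
                               body_water = 0.70) {
  if (sum(lung_mask) == 0L || sum(body_mask) == 0L)
    stop_lungecv("lung and body masks must be nonempty")
  if (any(lung_mask & body_mask))
    stop_lungecv("lung and body masks must be disjoint")
  med <- stats::median(corrected[body_mask])
  if (!is.finite(med) || med <= 0)
    stop_lungecv("body median signal is zero; cannot normalize")
  lwd <- array(NA_real_, dim = dim(corrected))
  lwd[lung_mask] <- body_water * corrected[lung_mask] / med
  n_flagged <- sum(lwd[lung_mask] > 1.2)
  if (n_flagged > 0)
    warning(sprintf("%d lung voxel(s) with water density > 1.2 (flagged)",
                    n_flagged), call. = FALSE)
  structure(list(lwd = lwd, global = mean(lwd[lung_mask]),
                 body_median = med, n_flagged = n_flagged,
                 body_water = body_water),
            class = "lwd_map")
}

#' @export
print.lwd_map <- function(x, ...) {
  cat(sprintf("lwd_map: global lung water density %.1f%% (%d flagged voxels)\n",
              100 * x$global, x$n_flagged))
  invisible(x)
}

#' Total lung water volume
#'
#' `lung water volume = lung water density x lung volume`, reported in mL.
#'
#' @param global_density lung water density (fraction).
#' @param lung_volume_l lung volume in litres.
#' @return lung water volume in mL.
#' @export
lung_water_volume <- function(global_density, lung_volume_l) {
  if (global_density < 0 || lung_volume_l <= 0)
    stop_lungecv("density must be nonnegative and lung volume positive")
  global_density * lung_volume_l * 1000
}

#' Extravascular lung water volume
#'
#' `extravascular lung water volume = ECV_extravascular x lung water volume`.
#'
#' @param ecv_ev extravascular ECV (fraction).
#' @param lwv_ml lung water volume (mL).
#' @return extravascular lung water volume in mL.
#' @export
extravascular_lung_water_volume <- function(ecv_ev, lwv_ml) {
  if (ecv_ev < 0 || lwv_ml < 0)
    stop_lungecv("inputs must be nonnegative")
  ecv_ev * lwv_ml
}
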