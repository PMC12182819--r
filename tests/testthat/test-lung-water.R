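test_that("constant shading comes out as the identity up to global scale", {
  ph <- uniform_phantom()
  pd <- simulate_proton_density(ph$map)$pd
  bref <- body_reference_mask(ph$map$body_mask, ph$map$lung_mask)
  sc0 <- shading_correction(pd, bref, order = 0L)
  expect_equal(sc0$corrected[bref] / pd[bref],
               rep(1 / mean(pd[bref]) * mean(pd[bref]), sum(bref)),
               tolerance = 1e-9)
  ratio <- sc0$corrected[bref] / pd[bref]
  expect_lt(diff(range(ratio)), 1e-9)
  sc2 <- shading_correction(2.5 * pd, bref, order = 2L)
  expect_equal(stats::sd(sc2$corrected[bref]) / mean(sc2$corrected[bref]),
               0, tolerance = 1e-9)
})

test_that("a known quadratic shading field is removed by the correction", {
  ph <- uniform_phantom()
  shading <- list(order = 2L,
                  coef = c(1, 0.15, -0.1, 0.2, 0.05, -0.12, 0.1, 0.05,
                           -0.05, -0.08))
  clean <- simulate_proton_density(ph$map)$pd
  shaded <- simulate_proton_density(ph$map, shading = shading)$pd
  bref <- body_reference_mask(ph$map$body_mask, ph$map$lung_mask)
  sc <- shading_correction(shaded, bref, order = 2L)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_gt(cv(shaded[bref]) / cv(sc$corrected[bref]), 10)
  # corrected lung/body ratio within 1% of the shading-free simulation
  r_clean <- mean(clean[ph$map$lung_mask]) / stats::median(clean[bref])
  r_corr <- mean(sc$corrected[ph$map$lung_mask]) /
    stats::median(sc$corrected[bref])
  expect_lt(abs(r_corr / r_clean - 1), 0.01)
})

test_that("degenerate shading fits are rejected", {
  pd <- array(1, c(4, 4, 4))
  thin <- array(FALSE, c(4, 4, 4)); thin[1, 1, ] <- TRUE
  expect_error(shading_correction(pd, thin, order = 2L), "degenerate")
  expect_error(shading_correction(pd, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("lung water density is the 0.70-scaled body-median ratio", {
  # lung voxel with water 0.30 inside a 0.70-water body, no shading/noise
  ph <- build_phantom("naive", params = phantom_params(
    "naive", lwd = 0.30, ap_gradient = 0, ev_gradient = 0))
  pd <- simulate_proton_density(ph$map)$pd
  bref <- body_reference_mask(ph$map$body_mask, ph$map$lung_mask)
  lwd <- lung_water_density(pd, ph$map$lung_mask, bref)
  expect_equal(lwd$global, 0.30, tolerance = 1e-9)
  expect_equal(unique(lwd$lwd[ph$map$lung_mask]), 0.30, tolerance = 1e-9)
  # an all-air voxel has zero density
  pd0 <- pd; pd0[which(ph$map$lung_mask)[1]] <- 0
  lwd0 <- lung_water_density(pd0, ph$map$lung_mask, bref)
  expect_equal(lwd0$lwd[which(ph$map$lung_mask)[1]], 0)
  # contracts
  expect_error(lung_water_density(pd, ph$map$lung_mask, ph$map$lung_mask),
               "disjoint")
  expect_error(lung_water_density(array(0, ph$map$dim), ph$map$lung_mask,
                                  bref), "zero")
  # implausibly bright lung voxels are flagged, never clipped
  hot <- pd; hot[ph$map$lung_mask] <- 2 * stats::median(pd[bref])
  expect_warning(l_hot <- lung_water_density(hot, ph$map$lung_mask, bref),
                 "flagged")
  expect_gt(l_hot$global, 1.2)
})

test_that("density is invariant to any global intensity scale", {
  ph <- naive_phantom()
  pd <- simulate_proton_density(ph$map, noise_sd = 0)$pd
  bref <- body_reference_mask(ph$map$body_mask, ph$map$lung_mask)
  l1 <- lung_water_density(pd, ph$map$lung_mask, bref)$global
  l2 <- lung_water_density(573.2 * pd, ph$map$lung_mask, bref)$global
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("lung water volumes are the stated products", {
  expect_equal(lung_water_volume(0.33, 0.93), 306.9, tolerance = 1e-9)
  expect_equal(lung_water_volume(0, 1), 0)
  expect_equal(lung_water_volume(0.33, 1.86), 2 * 306.9, tolerance = 1e-9)
  expect_equal(extravascular_lung_water_volume(0.27, 392), 105.84,
               tolerance = 1e-9)
  expect_equal(extravascular_lung_water_volume(0, 392), 0)
  expect_error(lung_water_volume(0.33, -1), "positive")
  expect_error(extravascular_lung_water_volume(-0.1, 392), "nonnegative")
})

test_that("the noiseless density chain reproduces the phantom truth", {
  ph <- naive_phantom()
  pd <- simulate_proton_density(ph$map, shading = NULL, noise_sd = 0)$pd
  bref <- body_reference_mask(ph$map$body_mask, ph$map$lung_mask)
  sc <- shading_correction(pd, bref)
  lwd <- lung_water_density(sc$corrected, ph$map$lung_mask, bref)
  expect_equal(lwd$global, ph$truth$lung_water_density, tolerance = 1e-6)
  lwv <- lung_water_volume(lwd$global, ph$truth$lung_volume_l)
  expect_lt(abs(lwv / ph$truth$lung_water_volume_ml - 1), 0.005)
})
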