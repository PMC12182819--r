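test_that("the ECV formula reproduces its worked identities", {
  # equal lung and blood delta-R1 at zero hematocrit gives 100%
  expect_equal(compute_ecv(8e-4, 8e-4, 1e-9 + 1e-6), 1, tolerance = 1e-5)
  # blood supplied as lung: ECV = 1 - Hct exactly
  expect_identical(compute_ecv(8e-4, 8e-4, 0.23), 1 - 0.23)
  # group-mean T1s of the naive arm (lung 931->559, blood 1199->609, Hct .23)
  ecv <- compute_ecv(as.numeric(delta_r1(559, 931)),
                     as.numeric(delta_r1(609, 1199)), 0.23)
  expect_equal(100 * ecv, 68.1, tolerance = 0.05)
  expect_error(compute_ecv(8e-4, 0, 0.23), "zero within tolerance")
  expect_error(compute_ecv(8e-4, 8e-4, 1.2), "hematocrit")
  expect_warning(compute_ecv(-2e-4, 8e-4, 0.23), "flagged")
})

test_that("hematocrit cancellation: common delta-R1 scaling leaves ECV unchanged", {
  for (k in c(0.5, 2, 10)) {
    expect_equal(compute_ecv(k * 7e-4, k * 8e-4, 0.23),
                 compute_ecv(7e-4, 8e-4, 0.23), tolerance = 1e-12)
  }
})

test_that("extravascular ECV is the exact subtraction, flagged when negative", {
  expect_equal(compute_ecv_extravascular(0.70, 0.43), 0.27, tolerance = 1e-12)
  expect_equal(compute_ecv_extravascular(0.78, 0.46), 0.32, tolerance = 1e-12)
  expect_identical(compute_ecv_extravascular(0.5, 0.5), 0)
  expect_warning(out <- compute_ecv_extravascular(0.40, 0.43), "negative")
  expect_equal(as.numeric(out), -0.03, tolerance = 1e-12)
  expect_error(compute_ecv_extravascular(NA_real_, 0.4), "finite")
})

test_that("ecv_result bundles a self-consistent dual-agent result", {
  t1 <- list(lung_native = 931, lung_gd = 559, lung_fe = 287,
             blood_native = 1199, blood_gd = 609, blood_fe = 199)
  r <- ecv_result(t1, 0.23, condition = "naive")
  expect_identical(r$ecv - r$pvf, r$ecv_ev)
  expect_false(r$flagged)
  expect_error(ecv_result(t1[-1], 0.23), "missing T1")
  # ferumoxytol delta-R1 of zero (no concentration) hits the error path
  t1$lung_fe <- t1$lung_native
  t1$blood_fe <- t1$blood_native
  expect_error(ecv_result(t1, 0.23), "zero within tolerance")
})

test_that("phase pairing follows the study rules", {
  man <- mr_manifest()
  pairs <- pair_phases(man)
  # two conditions x two agents
  expect_equal(nrow(pairs), 4L)
  expect_setequal(unique(pairs$condition),
                  c("baseline", "mitral_regurgitation"))
  expect_setequal(unique(pairs$agent), c("gadolinium", "ferumoxytol"))
  # each ECV uses the native map of its own condition
  for (i in seq_len(nrow(pairs))) {
    nat <- man$subjects[[1]]$volumes[[pairs$native_key[i]]]
    expect_equal(nat$phase, "native")
    expect_equal(nat$condition, pairs$condition[i])
  }
  expect_false(any(pairs$order_variant))

  # missing native errors with the absent map named
  man2 <- mr_manifest()
  man2$subjects[[1]]$volumes <- Filter(
    function(v) !(v$phase == "native" && v$condition == "baseline"),
    man2$subjects[[1]]$volumes)
  expect_error(pair_phases(man2), "missing native.*baseline")

  # ferumoxytol-first naive protocol is resolvable but order-variant
  man3 <- list(subjects = list(list(
    id = "pig2", model = "naive", hematocrit = 0.23,
    volumes = list(
      list(phase = "native", condition = "naive", order = 1, series = "n.nii"),
      list(phase = "ferumoxytol", condition = "naive", order = 2,
           series = "f.nii"),
      list(phase = "gadolinium", condition = "naive", order = 3,
           series = "g.nii")))))
  p3 <- pair_phases(man3)
  expect_true(all(p3$order_variant))
})

test_that("regional thirds partition the AP extent with a posterior remainder", {
  mk <- function(n) {
    m <- array(FALSE, c(2, n + 4, 1))
    m[, 3:(n + 2), ] <- TRUE
    m
  }
  b10 <- attr(regional_sections(mk(10)), "bounds")
  expect_equal(b10$end - b10$start + 1L, c(3L, 3L, 4L))
  b11 <- attr(regional_sections(mk(11)), "bounds")
  expect_equal(b11$end - b11$start + 1L, c(3L, 4L, 4L))
  b12 <- attr(regional_sections(mk(12)), "bounds")
  expect_equal(b12$end - b12$start + 1L, c(4L, 4L, 4L))
  expect_error(regional_sections(mk(2)), "below 3")
  expect_error(regional_sections(array(FALSE, c(2, 2, 2))), "empty")
  # sections are disjoint and cover the mask
  secs <- regional_sections(mk(10))
  expect_equal(sum(secs$anterior) + sum(secs$mid) + sum(secs$posterior),
               sum(mk(10)))
  expect_false(any(secs$anterior & secs$mid))
})

test_that("a uniform lung yields identical regional ECV everywhere", {
  ph <- uniform_phantom()
  maps <- local({
    av <- with(ph$map, f_ic + f_ev + f_pl)
    mask <- ph$map$lung_mask | ph$map$blood_mask
    lapply(stats::setNames(nm = c("native", "gadolinium", "ferumoxytol")),
           function(p) {
             tv <- simulate_t1_volume(ph$map, contrast_phase(p))
             fit_t1(simulate_sasha_series(tv$t1, av, sasha_protocol(),
                                          lung_mask = ph$map$lung_mask),
                    mask = mask)
           })
  })
  secs <- regional_sections(ph$map$lung_mask, ph$map$ap_axis)
  ecvs <- vapply(secs, function(m) {
    r <- ecv_result(roi_t1_list(maps, m, ph$map$blood_mask),
                    ph$map$hematocrit)
    r$ecv
  }, numeric(1))
  expect_lt(diff(range(ecvs)), 1e-6)
})
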