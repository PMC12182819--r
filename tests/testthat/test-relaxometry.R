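test_that("noiseless fits invert the generating parameters", {
  acq <- sasha_protocol()
  grid <- c(200, 287, 559, 931, 1199, 1300)
  t1v <- array(grid, c(length(grid), 1, 1))
  a <- array(1, dim = dim(t1v))
  ser <- simulate_sasha_series(t1v, a, acq)
  fit <- fit_t1(ser)
  expect_lt(max(abs(fit$t1 - t1v)), 1e-3)
  expect_true(all(fit$valid))
  expect_equal(as.vector(fit$b), rep(1, length(grid)), tolerance = 1e-6)

  # imperfect saturation: 3-parameter recovers (T1, B); 2-parameter is biased
  acq95 <- sasha_protocol(b = 0.95)
  ser95 <- simulate_sasha_series(array(559, c(1, 1, 1)),
                                 array(1, c(1, 1, 1)), acq95)
  f3 <- fit_t1(ser95, model = "3param")
  expect_equal(f3$t1[1], 559, tolerance = 1e-3)
  expect_equal(f3$b[1], 0.95, tolerance = 1e-6)
  f2 <- fit_t1(ser95, model = "2param")
  expect_gt(abs(f2$t1[1] - 559), 5)
})

test_that("the profiled fit agrees with Levenberg-Marquardt on noisy voxels", {
  acq <- sasha_protocol(snr = 15)
  n <- 12L
  ser <- simulate_sasha_series(array(800, c(n, 1, 1)), array(1, c(n, 1, 1)),
                               acq, seed = 21)
  fit <- fit_t1(ser, rician_correction = FALSE)
  ts <- ser$ts_ms
  w <- ser$averages
  for (i in seq_len(n)) {
    y <- ser$frames[i, 1, 1, ]
    ref <- minpack.lm::nlsLM(
      y ~ A * (1 - B * exp(-ts / t1)),
      start = list(A = max(y), B = 1, t1 = 800),
      weights = w, control = minpack.lm::nls.lm.control(maxiter = 200))
    expect_equal(fit$t1[i], unname(stats::coef(ref)["t1"]), tolerance = 1e-4)
  }
})

test_that("fits at moderate SNR recover the true T1 within 2%", {
  acq <- sasha_protocol(snr = 20)
  n <- 1000L
  ser <- simulate_sasha_series(array(900, c(n, 1, 1)), array(1, c(n, 1, 1)),
                               acq, seed = 42)
  fit <- fit_t1(ser)
  expect_lt(abs(stats::median(fit$t1[fit$valid]) / 900 - 1), 0.02)
  # ROI of 500 voxels: mean within 2%
  expect_lt(abs(mean(fit$t1[1:500][fit$valid[1:500]]) / 900 - 1), 0.02)
})

test_that("fit preconditions and validity flags are enforced", {
  acq <- sasha_protocol(ts_ms = c(104, 200), averages = c(8, 4),
                        anchor = FALSE)
  ser <- simulate_sasha_series(array(900, c(1, 1, 1)), array(1, c(1, 1, 1)),
                               acq)
  expect_error(fit_t1(ser, model = "3param"), "distinct saturation times")
  f2 <- fit_t1(ser, model = "2param")
  expect_equal(f2$t1[1], 900, tolerance = 1e-3)
  # a zero-signal voxel is flagged invalid, not fitted to nonsense
  ser0 <- simulate_sasha_series(array(900, c(2, 1, 1)),
                                array(c(1, 0), c(2, 1, 1)), sasha_protocol())
  f0 <- fit_t1(ser0)
  expect_true(f0$valid[1])
  expect_false(f0$valid[2])
})

test_that("ROI T1 averages valid voxels and errors on empty input", {
  ph <- naive_phantom()
  maps <- naive_noiseless_maps()
  lm <- ph$map$lung_mask
  expect_equal(roi_t1(maps$native, lm), 931, tolerance = 1e-3)
  # invalid voxels are excluded from the mean
  m <- maps$native
  sel <- which(lm)[1:10]
  m$valid[sel] <- FALSE
  m$t1[sel] <- 5e5
  expect_equal(roi_t1(m, lm), 931, tolerance = 1e-3)
  expect_error(roi_t1(maps$native, array(FALSE, dim = ph$map$dim)), "empty")
})

test_that("delta-R1 reproduces the worked arithmetic and its contracts", {
  expect_equal(as.numeric(delta_r1(559, 931)), 7.148e-4, tolerance = 1e-3)
  expect_equal(as.numeric(delta_r1(287, 931)), 2.410e-3, tolerance = 1e-3)
  expect_equal(as.numeric(delta_r1(931, 931)), 0)
  expect_error(delta_r1(-5, 931), "positive")
  expect_error(delta_r1(559, 0), "positive")
})

test_that("sequential contrast administration shortens T1 and grows delta-R1", {
  ph <- naive_phantom()
  maps <- naive_noiseless_maps()
  t1 <- roi_t1_list(maps, ph$map$lung_mask, ph$map$blood_mask)
  expect_true(t1$lung_gd < t1$lung_native)
  expect_true(t1$lung_fe < t1$lung_gd)
  dr1_gd <- as.numeric(delta_r1(t1$lung_gd, t1$lung_native))
  dr1_fe <- as.numeric(delta_r1(t1$lung_fe, t1$lung_native))
  expect_true(dr1_fe > dr1_gd && dr1_gd > 0)
  # adding concentration strictly decreases fitted T1
  hi <- simulate_t1_volume(ph$map, contrast_phase("gadolinium",
                                                  conc_gd = 0.5))
  lo <- simulate_t1_volume(ph$map, contrast_phase("gadolinium",
                                                  conc_gd = 0.25))
  expect_true(all(hi$t1[ph$map$lung_mask] < lo$t1[ph$map$lung_mask]))
})

test_that("Bloch readout reduces to ideal saturation recovery at zero flip", {
  b <- bloch_simulate_sasha(931, 40, flip_deg = 0)
  expect_equal(b$signal, 1 - exp(-b$ts_ms / 931), tolerance = 1e-12)
  # long saturation times approach the fully recovered steady signal
  b2 <- bloch_simulate_sasha(931, 40, ts_ms = c(3000, 6000, 12000))
  expect_lt(abs(b2$signal[3] - b2$signal[2]), 0.01 * b2$signal[3])
  expect_error(bloch_simulate_sasha(30, 40), "T1 >= T2")
})

test_that("fitted T1 is monotone in true T1 at protocol settings", {
  grid <- seq(200, 1300, by = 100)
  fitted <- vapply(grid, function(t1) {
    s <- bloch_simulate_sasha(t1, 40)
    ser <- list(frames = array(s$signal, c(1, 1, 1, nrow(s))),
                ts_ms = s$ts_ms, averages = c(8, 4, 4, 1), noise_sd = 0)
    fit_t1(ser)$t1[1]
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("Monte-Carlo precision table behaves physically", {
  expect_error(monte_carlo_t1(900, 20, n_reps = 50), "at least 100")
  mc <- monte_carlo_t1(c(287, 1199), c(10, 30), n_reps = 400, seed = 8)
  # SD decreases with SNR at fixed T1
  for (t1 in c(287, 1199)) {
    sd_by_snr <- mc$sd_ms[mc$t1_true == t1][order(c(10, 30))]
    expect_true(sd_by_snr[2] < sd_by_snr[1])
  }
  # short T1 is better sampled by the protocol's saturation times
  snr <- 10
  expect_lt(abs(mc$bias_ms[mc$t1_true == 287 & mc$snr == snr]),
            abs(mc$bias_ms[mc$t1_true == 1199 & mc$snr == snr]))
})
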