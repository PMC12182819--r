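# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# naive phantom with study-condition defaults
naive_phantom <- function() fixture("naive_phantom", function() {
  build_phantom("naive")
})

# spatially uniform naive phantom (no AP gradients)
uniform_phantom <- function() fixture("uniform_phantom", function() {
  build_phantom("naive", params = phantom_params("naive", ap_gradient = 0,
                                                 ev_gradient = 0))
})

# noiseless T1 maps for all three phases of the naive phantom
naive_noiseless_maps <- function() fixture("naive_noiseless_maps", function() {
  ph <- naive_phantom()
  av <- with(ph$map, f_ic + f_ev + f_pl)
  mask <- ph$map$lung_mask | ph$map$blood_mask
  lapply(stats::setNames(nm = c("native", "gadolinium", "ferumoxytol")),
         function(p) {
           tv <- simulate_t1_volume(ph$map, contrast_phase(p))
           ser <- simulate_sasha_series(tv$t1, av, sasha_protocol(),
                                        lung_mask = ph$map$lung_mask)
           fit_t1(ser, mask = mask)
         })
})

# ROI T1 list in the shape ecv_result() expects
roi_t1_list <- function(maps, lung, blood) {
  list(lung_native = roi_t1(maps$native, lung),
       lung_gd = roi_t1(maps$gadolinium, lung),
       lung_fe = roi_t1(maps$ferumoxytol, lung),
       blood_native = roi_t1(maps$native, blood),
       blood_gd = roi_t1(maps$gadolinium, blood),
       blood_fe = roi_t1(maps$ferumoxytol, blood))
}

# full noiseless measurement chain on a phantom: returns the ecv_result
measure_phantom <- function(ph, snr = Inf, seed = NULL) {
  av <- with(ph$map, f_ic + f_ev + f_pl)
  mask <- ph$map$lung_mask | ph$map$blood_mask
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  maps <- list()
  phases <- c("native", "gadolinium", "ferumoxytol")
  for (i in seq_along(phases)) {
    tv <- simulate_t1_volume(ph$map, contrast_phase(phases[i]))
    ser <- simulate_sasha_series(tv$t1, av, sasha_protocol(snr = snr),
                                 lung_mask = ph$map$lung_mask,
                                 seed = seeds[[i]])
    maps[[phases[i]]] <- fit_t1(ser, mask = mask)
  }
  ecv_result(roi_t1_list(maps, ph$map$lung_mask, ph$map$blood_mask),
             ph$map$hematocrit)
}

# a minimal two-condition (baseline / regurgitation) manifest skeleton for
# pairing tests; file paths are placeholders
mr_manifest <- function() {
  vol <- function(phase, cond, ord)
    list(phase = phase, condition = cond, order = ord,
         series = sprintf("%s_%s.nii", phase, cond))
  list(subjects = list(list(
    id = "pig1", model = "mitral_regurgitation", hematocrit = 0.26,
    volumes = list(vol("native", "baseline", 1),
                   vol("native", "mitral_regurgitation", 2),
                   vol("gadolinium", "baseline", 3),
                   vol("gadolinium", "mitral_regurgitation", 4),
                   vol("ferumoxytol", "baseline", 5),
                   vol("ferumoxytol", "mitral_regurgitation", 6)))))
}
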