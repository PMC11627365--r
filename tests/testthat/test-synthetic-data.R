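test_that("spec constructors validate their invariants", {
  expect_error(embryo_spec(semi_axes = c(15, 25)), "a > b")
  expect_error(embryo_spec(noise_sd = -1), "noise_sd")
  expect_error(embryo_spec(cytoplasm = -5), "cytoplasm")
  expect_error(membrane_model(-1, 0), "plateau")
  expect_error(membrane_model(1, 1, boundary = 0.7), "boundary")
  expect_error(embryo_spec(canvas_px = c(40, 40)), "canvas")
  expect_error(cohort_spec(n_embryos = 0), "n_embryos")
  expect_error(
    cohort_spec(phenotype_map = list(p = list(p_min = 0, p_wt = 1,
                                              K = 2, n = 6))),
    "K"
  )
})

test_that("rendered profiles follow the analytic Gauss + erf forward model", {
  spec <- embryo_spec(membrane = membrane_model(100, 100), cytoplasm = 50,
                      noise_sd = 0, seed = 1)
  re <- render_embryo(spec)
  m <- get_channel(re$image, "signal")
  px <- spec$pixel_size
  # middle row crosses the membrane at the two long-axis poles; compare the
  # peak against the analytic maximum of 100 * G(d) + 25 * (1 + erf(-d/..))
  d <- seq(-3, 3, by = 0.001)
  peak_true <- max(profile_model(d, 100, 50, w_g = 0.5, w_e = 0.5))
  mid <- m[nrow(m) / 2, ]
  expect_lt(abs(max(mid) / peak_true - 1), 0.01)
  # max intensity along normals is constant in s: compare rows of the
  # straightened raster (standard circular smoothing, bicubic sampling)
  ct <- segment_embryo(re$image, anterior = "left")
  st <- straighten_cortex(re$image, ct, interp = "bicubic")
  row_max <- apply(st$values, 1, max)
  expect_lt(max(row_max) / min(row_max) - 1, 0.01)
  expect_lt(abs(mean(row_max) / peak_true - 1), 0.01)
})

test_that("membrane-free render gives a pure step with ~zero fitted amplitude", {
  spec <- embryo_spec(membrane = membrane_model(0, 0), cytoplasm = 50,
                      noise_sd = 0, seed = 1)
  re <- render_embryo(spec)
  ct <- segment_embryo(re$image, anterior = "left", refine = "none")
  st <- straighten_cortex(re$image, ct)
  pr <- fit_membrane_profiles(st)
  expect_lt(mean(pr$positions$A, na.rm = TRUE), 1)
  expect_gt(mean(pr$positions$C, na.rm = TRUE), 45)
})

test_that("rendering is deterministic in the seed", {
  spec1 <- embryo_spec(noise_sd = 3, seed = 7)
  spec2 <- embryo_spec(noise_sd = 3, seed = 7)
  spec3 <- embryo_spec(noise_sd = 3, seed = 8)
  r1 <- render_embryo(spec1)$image
  r2 <- render_embryo(spec2)$image
  r3 <- render_embryo(spec3)$image
  expect_identical(r1$channels, r2$channels)
  expect_false(identical(r1$channels$signal, r3$channels$signal))
})

test_that("ground truth records the estimands the pipeline measures", {
  sp <- polarized_embryo_spec(0.6, seed = 2)
  re <- render_embryo(sp)
  tr <- re$truth
  expect_equal(tr$asi_true, 0.6, tolerance = 1e-8)
  expect_named(tr$A_true, c("apar", "ppar"))
  expect_true(all(c("mean_interior", "boundary_true", "s_grid") %in%
                    names(tr)))
  expect_error(polarized_embryo_spec(0.999), "not realizable")
})

test_that("rundown cohort follows the Hill map at its anchor points", {
  spec <- cohort_spec(n_embryos = 20, noise_sd = c(asynchrony_s = 0,
                                                   ab_fraction = 0, asi = 0),
                      seed = 1)
  at1 <- simulate_rundown_cohort(spec, dosages = rep(1, 20))$cohort
  # Hill(1) with K = 0.5, n = 6: p_wt * 1 / (1 + 0.5^6)
  expect_equal(at1$asynchrony_s, rep(120 / (1 + 0.5^6), 20),
               tolerance = 1e-12)
  at0 <- simulate_rundown_cohort(spec, dosages = rep(0, 20))$cohort
  expect_equal(at0$asynchrony_s, rep(0, 20), tolerance = 1e-12)
  expect_equal(at0$ab_fraction, rep(0.5, 20), tolerance = 1e-12)
})

test_that("default Hill map is steepest near 50% dosage", {
  # finite difference on noiseless Hill evaluations
  d <- seq(0.01, 1, by = 0.001)
  p <- hill_phenotype(d, 0, 1, K = 0.5, n = 6)
  steepest <- d[which.max(abs(diff(p)))]
  expect_lt(abs(steepest - 0.5), 0.05)
})

test_that("bimodal ASI regime matches its window model", {
  spec <- cohort_spec(n_embryos = 3000, noise_sd = c(asi = 0), seed = 3)
  sim <- simulate_rundown_cohort(spec)
  co <- sim$cohort
  expect_true(all(co$asi_retained[co$dosage_true > 0.75]))
  expect_false(any(co$asi_retained[co$dosage_true < 0.25]))
  # retained draws sit at wild-type level, lost draws scale with dosage
  expect_true(all(co$asi[co$asi_retained] > 0.9))
  lost <- !co$asi_retained
  expect_equal(co$asi[lost], 0.95 * co$dosage_true[lost] / 0.75,
               tolerance = 1e-12)
  # retention probability falls linearly across the window
  mid <- co$dosage_true > 0.45 & co$dosage_true < 0.55
  expect_equal(mean(co$asi_retained[mid]), 0.5, tolerance = 0.1)
})

test_that("simulated spindle tracks honour their analytic ground truth", {
  # zero amplitude, zero noise: y identically 0
  tr0 <- simulate_spindle_track(amplitude_um = 0, noise_sd = 0, seed = 1)
  expect_equal(tr0$frames$y_P, rep(0, nrow(tr0$frames)))
  # whole periods, dense sampling: population SD = a / sqrt(2) within 1%
  tr <- simulate_spindle_track(duration_s = 200, frame_interval_s = 0.1,
                               amplitude_um = 3, frequency_hz = 0.05,
                               drift_um_per_s = c(A = 0, P = 0),
                               noise_sd = 0, seed = 1)
  y <- tr$frames$y_P
  popsd <- sqrt(mean((y - mean(y))^2))
  expect_lt(abs(popsd / (3 / sqrt(2)) - 1), 0.01)
  # constant drift: displacement over any 1 s window is v * 1 s
  trd <- simulate_spindle_track(duration_s = 10, frame_interval_s = 0.1,
                                amplitude_um = 0,
                                drift_um_per_s = c(A = 0.5, P = 0.5),
                                noise_sd = 0, seed = 1)
  x <- trd$frames$x_A
  expect_equal(x[11] - x[1], 0.5, tolerance = 1e-10)
  expect_error(simulate_spindle_track(frame_interval_s = 0),
               "frame_interval")
})

test_that("two-cell simulation hits the target area fraction and asynchrony", {
  eq <- simulate_two_cell(0.5)
  expect_equal(sum(eq$mask_AB), sum(eq$mask_P1))
  tc <- simulate_two_cell(0.57, canvas_px = c(240, 400))
  frac <- sum(tc$mask_AB) / sum(tc$mask_whole)
  expect_lt(abs(frac - 0.57), 0.005)
  expect_true(all(tc$mask_AB | tc$mask_P1 | !tc$mask_whole))
  expect_false(any(tc$mask_AB & tc$mask_P1))
  # 120 s at 15 s/frame: event frames differ by 8
  expect_equal(unname(diff(tc$event_frames)), 8)
  expect_error(simulate_two_cell(1.2), "ab_fraction")
})
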