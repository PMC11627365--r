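test_that("segmentation recovers ellipse geometry to subpixel accuracy", {
  re <- render_embryo(embryo_spec(noise_sd = 0, seed = 1))
  ct <- segment_embryo(re$image, anterior = "left")
  a <- 25
  b <- 15
  h <- ((a - b) / (a + b))^2
  p_ramanujan <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  expect_lt(abs(ct$perimeter_um / p_ramanujan - 1), 0.01)
  area_um2 <- sum(ct$mask) * re$image$pixel_size^2
  expect_lt(abs(area_um2 / (pi * a * b) - 1), 0.01)
  expect_false(ct$border_touch)
  # blank image fails
  blank <- embryo_image(list(signal = matrix(0, 100, 100)), 0.256)
  expect_error(segment_embryo(blank), "segmentation failure")
})

test_that("anterior pole anchoring follows the marker channel", {
  sp <- polarized_embryo_spec(0.8, seed = 4)
  re <- render_embryo(sp)
  ct_a <- segment_embryo(re$image, channel = c("apar", "ppar"),
                         anterior_channel = "apar", anterior_marker = TRUE)
  # the aPAR profile should peak near s = 0 under correct anchoring
  pr <- fit_membrane_profiles(straighten_cortex(re$image, ct_a,
                                                channel = "apar"))
  expect_gt(cortical_mean(pr, "anterior"), cortical_mean(pr, "posterior"))
  # anchoring on the posterior marker flips the parameterization
  ct_p <- segment_embryo(re$image, channel = c("apar", "ppar"),
                         anterior_channel = "ppar", anterior_marker = FALSE)
  pr_p <- fit_membrane_profiles(straighten_cortex(re$image, ct_p,
                                                  channel = "apar"))
  expect_gt(cortical_mean(pr_p, "anterior"), cortical_mean(pr_p, "posterior"))
})

test_that("straightening contracts: constant image, identity window, errors", {
  re <- render_embryo(embryo_spec(noise_sd = 0, seed = 1))
  ct <- segment_embryo(re$image, anterior = "left")
  const <- embryo_image(list(signal = matrix(7, nrow(ct$mask), ncol(ct$mask))),
                        re$image$pixel_size)
  st <- straighten_cortex(const, ct)
  expect_equal(st$values, matrix(7, nrow(st$values), ncol(st$values)),
               tolerance = 1e-12)
  # smooth_window_px = 1 equals raw sampling exactly
  st_raw <- straighten_cortex(re$image, ct, smooth_window_px = 1)
  st_raw2 <- straighten_cortex(re$image, ct, smooth_window_px = 1)
  expect_identical(st_raw$values, st_raw2$values)
  # x runs outside -> inside across a 12.8 um window at defaults
  expect_equal(diff(range(st$x)), 49 * 0.256, tolerance = 1e-12)
  # normals exiting the canvas raise an error listing positions
  tight <- render_embryo(embryo_spec(noise_sd = 0, seed = 1, margin_um = 3))
  ct2 <- segment_embryo(tight$image, anterior = "left")
  expect_error(straighten_cortex(tight$image, ct2, width_px = 50),
               "exit the image")
})

test_that("circular smoothing conserves each column's perimeter mean", {
  re <- render_embryo(embryo_spec(noise_sd = 2, seed = 2))
  ct <- segment_embryo(re$image, anterior = "left")
  raw <- straighten_cortex(re$image, ct, smooth_window_px = 1)
  sm <- straighten_cortex(re$image, ct, smooth_window_px = 20)
  expect_equal(colMeans(sm$values), colMeans(raw$values), tolerance = 1e-10)
})

test_that("profile decomposition recovers known amplitudes", {
  # noiseless: exact within numerical tolerance
  st0 <- make_profile_raster(100, C = 50, noise_sd = 0)
  pr0 <- fit_membrane_profiles(st0)
  expect_lt(sqrt(mean((pr0$positions$A / 100 - 1)^2)), 0.005)
  expect_lt(sqrt(mean((pr0$positions$C / 50 - 1)^2)), 0.005)
  # noise SD 2: RMS relative error < 5% over 100 positions
  st <- make_profile_raster(100, C = 50, noise_sd = 2, seed = 11)
  pr <- fit_membrane_profiles(st)
  expect_lt(sqrt(mean((pr$positions$A / 100 - 1)^2)), 0.05)
  # step-only profile: amplitude at the noise floor
  stA0 <- make_profile_raster(0, C = 50, noise_sd = 1, seed = 12)
  prA0 <- fit_membrane_profiles(stA0)
  expect_lt(mean(prA0$positions$A), 2)
  # linearity: doubling intensities doubles A and C (noiseless)
  st2 <- st0
  st2$values <- 2 * st0$values
  pr2 <- fit_membrane_profiles(st2)
  expect_equal(pr2$positions$A, 2 * pr0$positions$A, tolerance = 1e-6)
  expect_equal(pr2$positions$C, 2 * pr0$positions$C, tolerance = 1e-6)
})

test_that("narrow rasters are rejected and flags propagate", {
  st <- make_profile_raster(100, width = 10)
  expect_error(fit_membrane_profiles(st), "20 samples")
})

test_that("cortical_mean integrates the stated pole arcs", {
  n <- 1000
  s <- seq(0, 1 - 1 / n, by = 1 / n)
  expect_equal(cortical_mean(rep(80, n), "anterior"), 80)
  expect_equal(cortical_mean(rep(80, n), "posterior"), 80)
  # block profile: A = 100 on s in [0.35, 0.65], else 0; f = 0.30
  A <- ifelse(s >= 0.35 & s <= 0.65, 100, 0)
  expect_equal(cortical_mean(A, "posterior", fraction = 0.30), 100,
               tolerance = 0.01)
  expect_equal(cortical_mean(A, "anterior", fraction = 0.30), 0)
  # fraction = 1 gives the global mean
  A2 <- runif(n)
  expect_equal(cortical_mean(A2, "anterior", fraction = 1), mean(A2))
})

test_that("total dosage is the control-normalized in-mask mean", {
  mask <- matrix(FALSE, 40, 40)
  mask[10:30, 10:30] <- TRUE
  img <- embryo_image(list(signal = matrix(50, 40, 40)), 0.256)
  expect_equal(total_dosage(img, mask, control_mean = 50), 1)
  img2 <- embryo_image(list(signal = matrix(25, 40, 40)), 0.256)
  expect_equal(total_dosage(img2, mask, control_mean = 50), 0.5)
  expect_error(total_dosage(img, mask, control_mean = 0), "positive")
  # generator round trip at true dosages 1 .. 0.25, noiseless
  scales <- c(1, 0.75, 0.5, 0.25)
  imgs <- lapply(seq_along(scales), function(i) {
    render_embryo(embryo_spec(
      membrane = membrane_model(100 * scales[i], 100 * scales[i]),
      cytoplasm = 30 * scales[i], noise_sd = 0, seed = i
    ))
  })
  ct1 <- segment_embryo(imgs[[1]]$image, anterior = "left")
  ctrl_mean <- mask_mean(imgs[[1]]$image, ct1$mask)
  for (i in seq_along(scales)) {
    ct <- segment_embryo(imgs[[i]]$image, anterior = "left")
    d <- total_dosage(imgs[[i]]$image, ct$mask, ctrl_mean)
    expect_lt(abs(d / scales[i] - 1), 0.02)
  }
})

test_that("dosage-binned profile averaging selects nearest embryos", {
  profs <- matrix(c(rep(10, 50), rep(20, 50), rep(30, 50), rep(40, 50)),
                  4, 50, byrow = TRUE)
  dos <- c(1.0, 0.8, 0.5, 0.2)
  out <- average_profiles_by_dosage(profs, dos, levels = c(1, 0.5), k = 1)
  expect_equal(out[[1]]$selected, 1)
  expect_equal(out[[1]]$mean, rep(10, 50))
  expect_equal(out[[1]]$sd, rep(0, 50))
  expect_equal(out[[2]]$selected, 3)
  # 7 identical profiles: mean equals the profile, SD = 0
  profs7 <- matrix(rep(5, 7 * 20), 7, 20)
  out7 <- average_profiles_by_dosage(profs7, rep(1, 7), levels = 1, k = 7)
  expect_equal(out7[[1]]$mean, rep(5, 20))
  expect_equal(out7[[1]]$sd, rep(0, 20))
  expect_error(average_profiles_by_dosage(profs, dos, k = 7), "at least")
})

test_that("cortical quantities are rotation invariant within 1%", {
  sp <- polarized_embryo_spec(0.6, noise_sd = 0, seed = 6)
  re <- render_embryo(sp)
  measure <- function(img) {
    ct <- segment_embryo(img, channel = c("apar", "ppar"),
                         anterior_channel = "apar")
    pr <- fit_membrane_profiles(straighten_cortex(img, ct, channel = "apar"))
    c(cortical_mean(pr, "anterior"), cortical_mean(pr, "posterior"))
  }
  m0 <- measure(re$image)
  m90 <- measure(rotate_image_90(re$image))
  expect_lt(max(abs(m90 / m0 - 1)), 0.01)
})

test_that("noiseless image round trip recovers A(s) within 2%", {
  sp <- polarized_embryo_spec(0.6, noise_sd = 0, seed = 3)
  re <- render_embryo(sp)
  ct <- segment_embryo(re$image, channel = c("apar", "ppar"),
                       anterior_channel = "apar")
  pr <- fit_membrane_profiles(straighten_cortex(re$image, ct,
                                                channel = "apar",
                                                interp = "bicubic"))
  A_true <- sp$membrane$apar$m_post +
    (sp$membrane$apar$m_ant - sp$membrane$apar$m_post) *
      plogis(sp$membrane$apar$sharpness *
               (sp$membrane$apar$boundary -
                  pmin(pr$positions$s, 1 - pr$positions$s)))
  away <- pmin(abs(pr$positions$s - 0.25), abs(pr$positions$s - 0.75)) > 0.08
  rel <- abs(pr$positions$A - A_true) / A_true
  expect_lt(max(rel[away]), 0.02)
  # with 2%-of-peak noise, 5% RMS away from the transition zone
  sp2 <- polarized_embryo_spec(0.6, noise_sd = 2, seed = 13)
  re2 <- render_embryo(sp2)
  ct2 <- segment_embryo(re2$image, channel = c("apar", "ppar"),
                        anterior_channel = "apar")
  pr2 <- fit_membrane_profiles(straighten_cortex(re2$image, ct2,
                                                 channel = "apar",
                                                 interp = "bicubic"))
  rel2 <- (pr2$positions$A - A_true) / A_true
  expect_lt(sqrt(mean(rel2[away]^2)), 0.05)
})
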