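test_that("composite ASI evaluates its formula and symmetries", {
  expect_equal(asi_composite(1, 0, 0, 1), 1)
  expect_equal(asi_composite(0.4, 0.4, 0.7, 0.7), 0)
  expect_equal(asi_composite(1, 0.5, 0.25, 0.75), 0.4)
  expect_error(asi_composite(0, 0, 0, 0), "denominator")
  # scale invariance and label-swap antisymmetry, over random cases
  set.seed(1)
  for (i in 1:20) {
    v <- runif(4, 0.01, 2)
    k <- runif(1, 0.1, 10)
    base <- asi_composite(v[1], v[2], v[3], v[4])
    expect_equal(asi_composite(k * v[1], k * v[2], k * v[3], k * v[4]),
                 base, tolerance = 1e-12)
    # swapping anterior/posterior labels (poles) flips the sign
    expect_equal(asi_composite(v[2], v[1], v[4], v[3]), -base,
                 tolerance = 1e-12)
  }
})

test_that("single-protein ASI respects protein sidedness and sign", {
  expect_equal(asi_single(1, 1, "anterior"), 0)
  expect_equal(asi_single(3, 1, "anterior"), 0.5)  # MEX-5 style
  expect_equal(asi_single(3, 1, "posterior"), -0.5) # PAR-1 inverted
  expect_equal(asi_single(1, 3, "posterior"), 0.5)
  expect_error(asi_single(0, 0, "anterior"), "positive")
  set.seed(2)
  for (i in 1:10) {
    v <- runif(2, 0.01, 5)
    k <- runif(1, 0.1, 10)
    expect_equal(asi_single(k * v[1], k * v[2], "anterior"),
                 asi_single(v[1], v[2], "anterior"), tolerance = 1e-12)
  }
})

test_that("gradient magnitude is the signed P - A difference", {
  expect_equal(gradient_magnitude(80, 80), 0)
  expect_equal(gradient_magnitude(120, 80), 40)
  # linear-in-dosage gradient generator: slope recovered within 5%
  set.seed(3)
  d <- runif(100)
  true_slope <- 35
  P <- 50 + true_slope * d + rnorm(100, 0, 1)
  A <- 50 + rnorm(100, 0, 1)
  dc <- gradient_magnitude(P, A)
  fit <- coef(lm(dc ~ d))
  expect_lt(abs(fit[["d"]] / true_slope - 1), 0.05)
})

test_that("domain boundary is found by half-max crossing", {
  n <- 1000
  s <- seq(0, 1 - 1 / n, by = 1 / n)
  # step: A = 100 on the anterior half arc s in [0.75, 1) U [0, 0.25]
  A <- ifelse(s <= 0.25 | s >= 0.75, 100, 0)
  db <- domain_boundary(A, s, "anterior")
  expect_equal(db$boundary, 0.25, tolerance = 0.002)
  # uniform: no boundary
  expect_equal(domain_boundary(rep(5, n), s, "anterior")$flag, "no_boundary")
  # logistic ground truth at s_b = 0.30, k = 20: within 0.01
  A_log <- 100 * plogis(20 * (0.30 - pmin(s, 1 - s)))
  db2 <- domain_boundary(A_log, s, "anterior")
  expect_lt(abs(db2$boundary - 0.30), 0.01)
  # mirrored profiles: anterior + posterior boundaries sum to ~0.5
  db_post <- domain_boundary(A_log, s, "posterior")
  expect_lt(abs(db2$boundary + db_post$boundary - 0.5), 0.01)
})

test_that("membrane:cytoplasm ratio matches the forward model", {
  re <- render_embryo(embryo_spec(membrane = membrane_model(150, 150),
                                  cytoplasm = 50, noise_sd = 0, seed = 1))
  img <- re$image
  m <- get_channel(img, "signal")
  nr <- nrow(m)
  nc <- ncol(m)
  px <- img$pixel_size
  # vertical linescan crossing the top membrane at the embryo midline
  row_mem <- (nr + 1) / 2 - 15 / px # membrane at y = +b
  line <- list(start = c(row_mem - 10, (nc + 1) / 2),
               end = c(row_mem + 10, (nc + 1) / 2), width_px = 10)
  roi <- matrix(FALSE, nr, nc)
  roi[(nr / 2 - 10):(nr / 2 + 10), (nc / 2 - 20):(nc / 2 + 20)] <- TRUE
  out <- mem_cyt_ratio(img, line, roi)
  # oracle: peak-5-sample mean of the analytic profile over cytoplasm 50
  d <- seq(-10, 10, length.out = 21) * px
  prof <- profile_model(d, 150, 50, w_g = 0.5, w_e = 0.5)
  peak5 <- max(stats::filter(prof, rep(1 / 5, 5), sides = 2), na.rm = TRUE)
  expect_lt(abs(out$ratio / (peak5 / 50) - 1), 0.03)
  # flat image: ratio 1
  flat <- embryo_image(list(signal = matrix(60, nr, nc)), px)
  expect_equal(mem_cyt_ratio(flat, line, roi)$ratio, 1, tolerance = 1e-9)
  # scale invariance
  img2 <- embryo_image(list(signal = 2 * m), px)
  expect_equal(mem_cyt_ratio(img2, line, roi)$ratio, out$ratio,
               tolerance = 1e-9)
  expect_error(mem_cyt_ratio(flat, line,
                             matrix(FALSE, nr, nc)), "positive")
})

test_that("domain calling classifies ratio traces", {
  n <- 1000
  s <- seq(0, 1 - 1 / n, by = 1 / n)
  t_ant <- pmin(s, 1 - s)
  expect_equal(detect_domains(rep(1, n), s)$category, "no_domains")
  expect_equal(detect_domains(rep(1.3, n), s)$category, "unclear")
  # single posterior domain at ratio 2: monopolar arc containing s = 0.5
  r_mono <- 1 + 1 * plogis(60 * (0.2 - abs(s - 0.5)))
  dm <- detect_domains(r_mono, s)
  expect_equal(dm$category, "monopolar")
  expect_true(dm$arcs$s_start[1] < 0.5 && dm$arcs$s_end[1] > 0.5)
  # two domains, one wrapping s = 0: bipolar
  r_bi <- 1 + plogis(60 * (0.1 - t_ant)) + plogis(60 * (0.1 - abs(s - 0.5)))
  expect_equal(detect_domains(r_bi, s)$category, "bipolar")
  # arcs shorter than min_arc are discarded
  r_tiny <- 1 + ifelse(abs(s - 0.5) < 0.01, 1, 0)
  expect_equal(detect_domains(r_tiny, s)$category, "unclear")
  expect_error(detect_domains(c(1, 2, 1, 1, 1), c(0, 0.5, 0.4, 0.6, 0.7)),
               "sorted")
})

test_that("measured ASI tracks ground truth across a rundown (RMSE < 0.05)", {
  # profile-level cohort: true membrane models -> noisy rasters -> fits ->
  # pole-arc means -> composite ASI, compared with the generating truth
  set.seed(7)
  taus <- runif(40, 0, 0.95)
  meas <- true <- numeric(length(taus))
  for (i in seq_along(taus)) {
    sp <- polarized_embryo_spec(taus[i], M = 100, cytoplasm = 30,
                                noise_sd = 0, seed = i)
    s <- seq(0, 1 - 1 / 200, by = 1 / 200)
    A_a <- parmap:::eval_membrane_model(sp$membrane$apar, s)
    A_p <- parmap:::eval_membrane_model(sp$membrane$ppar, s)
    st_a <- make_profile_raster(A_a, C = 30, n_pos = 200, noise_sd = 2,
                                seed = 1000 + i)
    st_p <- make_profile_raster(A_p, C = 30, n_pos = 200, noise_sd = 2,
                                seed = 2000 + i)
    pr_a <- fit_membrane_profiles(st_a)
    pr_p <- fit_membrane_profiles(st_p)
    pk <- 100
    meas[i] <- asi_composite(
      cortical_mean(pr_a, "anterior") / pk,
      cortical_mean(pr_a, "posterior") / pk,
      cortical_mean(pr_p, "anterior") / pk,
      cortical_mean(pr_p, "posterior") / pk
    )
    true[i] <- taus[i]
  }
  expect_lt(sqrt(mean((meas - true)^2)), 0.05)
})
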