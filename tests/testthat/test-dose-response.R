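test_that("compensation fraction evaluates its definition", {
  expect_equal(compensation_fraction(1, 0.5, 0.5)$fraction, 0)
  expect_equal(compensation_fraction(1, 0.5, 1)$fraction, 1)
  expect_equal(compensation_fraction(1.0, 0.5, 0.6)$fraction, 0.2)
  expect_error(compensation_fraction(0.5, 0.5, 0.6), "denominator")
  # invariance to common rescaling
  set.seed(1)
  for (i in 1:10) {
    v <- sort(runif(3, 0.1, 2))
    k <- runif(1, 0.1, 10)
    expect_equal(
      compensation_fraction(k * v[3], k * v[1], k * v[2])$fraction,
      compensation_fraction(v[3], v[1], v[2])$fraction,
      tolerance = 1e-12
    )
  }
  # outside-unit values flagged, not rejected
  expect_equal(compensation_fraction(1, 0.5, 0.4)$flag,
               "outside_unit_interval")
  # delta-method CI brackets the estimate and shrinks with SEM
  cf <- compensation_fraction(1, 0.5, 0.6,
                              sem = c(hom = 0.02, het_wt = 0.02,
                                      het_null = 0.02))
  expect_true(cf$ci[["lower"]] < 0.2 && cf$ci[["upper"]] > 0.2)
  cf2 <- compensation_fraction(1, 0.5, 0.6,
                               sem = c(hom = 0.002, het_wt = 0.002,
                                       het_null = 0.002))
  expect_lt(cf2$se, cf$se)
})

test_that("dosage normalization maps controls to mean 1", {
  ctrl <- c(90, 100, 110)
  expect_equal(mean(normalize_dosage(ctrl, ctrl)), 1)
  expect_equal(normalize_dosage(25, ctrl), 0.25)
  expect_error(normalize_dosage(1, numeric(0)), "empty")
})

test_that("LOWESS is exact on linear data and OLS with a flat kernel", {
  set.seed(2)
  x <- runif(50)
  y <- 2 * x
  tf <- lowess_bootstrap(x, y, span = 0.5, n_boot = 20, seed = 1)
  expect_lt(max(abs(tf$grid$fit - 2 * tf$grid$x)), 1e-8)
  expect_lt(max(tf$grid$upper - tf$grid$lower), 1e-8)
  # constant y
  tfc <- lowess_bootstrap(x, rep(3, 50), span = 0.5, n_boot = 20, seed = 1)
  expect_lt(max(abs(tfc$grid$fit - 3)), 1e-10)
  # flat kernel with span 1 reproduces ordinary least squares
  yn <- 2 * x + rnorm(50, 0, 0.3)
  tfo <- lowess_bootstrap(x, yn, span = 1, n_boot = 10, seed = 1,
                          kernel = "flat")
  ols <- lm(yn ~ x)
  expect_equal(tfo$grid$fit, unname(predict(ols,
                                            data.frame(x = tfo$grid$x))),
               tolerance = 1e-8)
  expect_error(lowess_bootstrap(x[1:5], y[1:5]), "at least 10")
  expect_error(lowess_bootstrap(rep(1, 20), rnorm(20)), "constant x")
  expect_error(lowess_bootstrap(x, y, span = 0.01), "span")
})

test_that("LOWESS agrees with stats::lowess as an independent cross-check", {
  set.seed(3)
  x <- sort(runif(150))
  y <- sin(2 * x) + rnorm(150, 0, 0.05)
  tf <- lowess_bootstrap(x, y, span = 1 / 3, n_boot = 10, seed = 1,
                         grid = x)
  ref <- lowess(x, y, f = 1 / 3, iter = 0)
  expect_lt(max(abs(tf$grid$fit - ref$y)), 0.02)
})

test_that("LOWESS tracks a Hill response and finds its inflection", {
  set.seed(4)
  x <- runif(200)
  y <- hill_phenotype(x) + rnorm(200, 0, 0.05)
  g <- seq(0.1, 1, length.out = 100)
  tf <- lowess_bootstrap(x, y, span = 0.3, n_boot = 50, seed = 1, grid = g)
  expect_lt(max(abs(tf$grid$fit - hill_phenotype(g))), 0.05)
  steepest <- g[which.max(abs(diff(tf$grid$fit)))]
  expect_lt(abs(steepest - 0.5), 0.05)
})

test_that("bootstrap bands are seed-reproducible", {
  set.seed(5)
  x <- runif(60)
  y <- x + rnorm(60, 0, 0.2)
  a <- lowess_bootstrap(x, y, n_boot = 50, seed = 42)
  b <- lowess_bootstrap(x, y, n_boot = 50, seed = 42)
  expect_identical(a$grid, b$grid)
  wa <- gaussian_window_stats(x, y, n_boot = 50, seed = 42)
  wb <- gaussian_window_stats(x, y, n_boot = 50, seed = 42)
  expect_identical(wa$grid, wb$grid)
  # bootstrap must not perturb the caller's RNG stream
  set.seed(9)
  before <- rnorm(1)
  set.seed(9)
  invisible(lowess_bootstrap(x, y, n_boot = 10, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("Gaussian-window stats match a direct-summation oracle", {
  oracle <- function(x, y, grid, sigma) {
    t(vapply(grid, function(x0) {
      w <- exp(-(x - x0)^2 / (2 * sigma^2))
      mx <- sum(w * x) / sum(w)
      my <- sum(w * y) / sum(w)
      c(mx, sum(w * (y - my)^2) / sum(w))
    }, numeric(2)))
  }
  set.seed(6)
  for (i in 1:20) {
    x <- runif(50)
    y <- rnorm(50)
    g <- seq(0, 1, length.out = 25)
    ws <- gaussian_window_stats(x, y, h = 0.1, grid = g, n_boot = 2,
                                seed = 1)
    ref <- oracle(x, y, g, 0.1)
    expect_lt(max(abs(ws$grid$mean_dosage - ref[, 1])), 1e-10)
    expect_lt(max(abs(ws$grid$variance - ref[, 2])), 1e-10)
  }
})

test_that("window limits: h -> Inf gives global variance, h -> 0 gives 0", {
  set.seed(7)
  x <- runif(40)
  y <- rnorm(40)
  wide <- gaussian_window_stats(x, y, h = 1e6, grid = 0.5, n_boot = 2,
                                seed = 1)
  expect_equal(wide$grid$variance, mean((y - mean(y))^2), tolerance = 1e-6)
  narrow <- gaussian_window_stats(x, y, h = 1e-9, grid = x[1], n_boot = 2,
                                  seed = 1)
  expect_lt(narrow$grid$variance, 1e-12)
  # constant y: variance 0 everywhere
  wc <- gaussian_window_stats(x, rep(2, 40), h = 0.1, n_boot = 2, seed = 1)
  expect_true(all(wc$grid$variance < 1e-20))
})

test_that("variance profile of a simulated rundown peaks near the inflection", {
  sim <- simulate_rundown_cohort(cohort_spec(n_embryos = 200, seed = 11))
  ws <- gaussian_window_stats(sim$cohort$dosage_true,
                              sim$cohort$asynchrony_s,
                              h = 0.1, n_boot = 50, seed = 1)
  peak <- ws$grid$mean_dosage[which.max(ws$grid$variance)]
  expect_lt(abs(peak - 0.5), 0.1)
})

test_that("FWHM interpretation of the half-width rescales sigma", {
  set.seed(8)
  x <- runif(30)
  y <- rnorm(30)
  g <- seq(0.2, 0.8, length.out = 5)
  ws_s <- gaussian_window_stats(x, y, h = 0.1 / sqrt(2 * log(2)), grid = g,
                                n_boot = 2, seed = 1)
  ws_f <- gaussian_window_stats(x, y, h = 0.1, grid = g, n_boot = 2,
                                seed = 1, interpretation = "fwhm")
  expect_equal(ws_s$grid$variance, ws_f$grid$variance, tolerance = 1e-12)
})
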