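#' Dosage compensation fraction
#'
#' Degree of excess signal in hemizygous (`xfp/-`) embryos expressed as the
#' fraction of the difference between homozygous (`xfp/xfp`) and
#' heterozygous-untagged (`xfp/+`) cohorts:
#' `(x_het_null - x_het_wt) / (x_hom - x_het_wt)`.  0 means no
#' compensation, 1 full compensation; values outside `[0, 1]` are permitted
#' and flagged.  When per-genotype SEMs are supplied, a delta-method 95% CI
#' is propagated.
#'
#' @param x_hom Cohort mean for `xfp/xfp`.
#' @param x_het_wt Cohort mean for `xfp/+`.
#' @param x_het_null Cohort mean for `xfp/-` (or `xfp/RNAi`).
#' @param sem Optional numeric vector
#'   `c(hom = ..., het_wt = ..., het_null = ...)` of standard errors.
#' @return A list with `fraction`, `flag` (`"outside_unit_interval"` or
#'   `"none"`), and (when `sem` given) `ci` (95%, delta method) and `se`.
#' @export
compensation_fraction <- function(x_hom, x_het_wt, x_het_null, sem = NULL) {
  if (!(x_hom > x_het_wt)) {
    stop("degenerate denominator: require x_hom > x_het_wt")
  }
  den <- x_hom - x_het_wt
  f <- (x_het_null - x_het_wt) / den
  out <- list(
    fraction = f,
    flag = if (f < 0 || f > 1) "outside_unit_interval" else "none"
  )
  if (!is.null(sem)) {
    sem <- sem[c("hom", "het_wt", "het_null")]
    if (anyNA(sem)) stop("`sem` must name hom, het_wt and het_null")
    d_hom <- -(x_het_null - x_het_wt) / den^2
    d_hwt <- (x_het_null - x_hom) / den^2
    d_hnl <- 1 / den
    se <- sqrt((d_hom * sem[["hom"]])^2 + (d_hwt * sem[["het_wt"]])^2 +
                 (d_hnl * sem[["het_null"]])^2)
    out$se <- se
    out$ci <- c(lower = f - 1.96 * se, upper = f + 1.96 * se)
  }
  out
}

#' Normalize dosages to the control-cohort mean
#'
#' @param values Per-embryo raw values (e.g. whole-embryo mean intensity).
#' @param control_values Values of the control cohort (mean must be > 0).
#' @return `values / mean(control_values)`, so controls average 1.
#' @export
normalize_dosage <- function(values, control_values) {
  if (length(control_values) == 0) stop("empty control cohort")
  cm <- mean(control_values)
  if (!is.finite(cm) || cm <= 0) stop("control mean must be positive")
  values / cm
}

# Local linear regression at grid points with span-fraction nearest
# neighbours; tricube kernel by default, flat kernel as a test hook.
local_linear_fit <- function(x, y, grid, span, kernel = c("tricube", "flat"),
                             robust_iter = 0) {
  kernel <- match.arg(kernel)
  n <- length(x)
  k <- max(3, ceiling(span * n))
  k <- min(k, n)
  rw <- rep(1, n)
  for (pass in 0:robust_iter) {
    yhat <- vapply(grid, function(x0) {
      d <- abs(x - x0)
      dk <- sort(d, partial = k)[k]
      w <- if (kernel == "flat") {
        as.numeric(d <= dk)
      } else if (dk == 0) {
        as.numeric(d == 0)
      } else {
        (1 - pmin(d / dk, 1)^3)^3
      }
      w <- w * rw
      use <- w > 0
      if (sum(use) < 2 || stats::var(x[use]) == 0) {
        return(sum(w * y) / sum(w))
      }
      cf <- stats::lm.wfit(cbind(1, x[use] - x0), y[use], w[use])$coefficients
      cf[1]
    }, numeric(1))
    if (pass < robust_iter) {
      fit_at_x <- stats::approx(grid, yhat, xout = x, rule = 2)$y
      res <- y - fit_at_x
      s6 <- 6 * stats::median(abs(res))
      rw <- if (s6 > 0) pmax(1 - (res / s6)^2, 0)^2 else rep(1, n)
    }
  }
  yhat
}

#' LOWESS dose-response trend with bootstrap confidence band
#'
#' Locally weighted linear regression (tricube weights over the
#' span-fraction nearest neighbours of each grid point) fitted to a
#' dosage-phenotype scatter, with a pointwise 95% percentile band from
#' case-resampling bootstrap replicates.  Deterministic given `seed`.
#'
#' @param x,y Dosage and phenotype vectors (finite, `length(x) >= 10`).
#' @param span Neighbourhood fraction (default 0.5).  Choose the span below
#'   the width of the sharpest feature to be resolved: spans much wider
#'   than a sigmoid transition bias the fit at its shoulders.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed (required for a band).
#' @param grid Evaluation grid; default 100 points spanning `range(x)`.
#' @param kernel `"tricube"`, or `"flat"` (with `span = 1` this reproduces
#'   ordinary least squares; exposed for verification).
#' @param robust_iter Robustness iterations (default 0).
#' @param conf Band coverage (default 0.95).
#' @return An object of class `trend_fit`: data frame `grid` with columns
#'   `x`, `fit`, `lower`, `upper`, plus the call parameters.
#' @export
lowess_bootstrap <- function(x, y, span = 0.5, n_boot = 1000, seed = 1L,
                             grid = NULL, kernel = c("tricube", "flat"),
                             robust_iter = 0, conf = 0.95) {
  kernel <- match.arg(kernel)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 10) stop("need at least 10 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("x and y must be finite")
  if (stats::var(x) == 0) stop("constant x: no trend to fit")
  if (span * length(x) < 3) stop("span too small: span * n must be >= 3")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100)

  fit <- local_linear_fit(x, y, grid, span, kernel, robust_iter)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(x), replace = TRUE)
      local_linear_fit(x[idx], y[idx], grid, span, kernel, robust_iter)
    }, numeric(length(grid)))
  })
  alpha <- (1 - conf) / 2
  lower <- apply(boots, 1, stats::quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(boots, 1, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  structure(
    list(
      grid = data.frame(x = grid, fit = fit,
                        lower = pmin(lower, fit), upper = pmax(upper, fit)),
      span = span, kernel = kernel, n_boot = n_boot, seed = seed,
      conf = conf, n = length(x)
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> LOWESS (%s kernel, span %.2f) on n = %d, %d-point grid, %d bootstrap reps\n",
    x$kernel, x$span, x$n, nrow(x$grid), x$n_boot
  ))
  invisible(x)
}

#' @export
plot.trend_fit <- function(x, add_band = TRUE, ...) {
  g <- x$grid
  graphics::plot(g$x, g$fit, type = "n", xlab = "dosage", ylab = "phenotype",
                 ylim = range(g$lower, g$upper), ...)
  if (add_band) {
    graphics::polygon(c(g$x, rev(g$x)), c(g$lower, rev(g$upper)),
                      col = "grey85", border = NA)
  }
  graphics::lines(g$x, g$fit, lwd = 2)
  invisible(x)
}

#' Gaussian moving-window weighted variance along the dosage axis
#'
#' A Gaussian weighting function of half-width `h` (interpreted as the
#' Gaussian SD; set `interpretation = "fwhm"` to read `h` as half of the
#' full width at half maximum) is moved along the dosage axis.  At each
#' window centre the Gaussian-weighted mean dosage is paired with the
#' Gaussian-weighted phenotypic variance
#' `sum(w * (y - weighted.mean(y, w))^2) / sum(w)`, and 95% confidence
#' intervals come from case-resampling bootstrap.  Phenotypic variance
#' peaks where the dose-response curve is steepest relative to the window,
#' e.g. near the inflection of a Hill-type response.
#'
#' @param x,y Dosage and phenotype vectors (`length(x) >= 10`).
#' @param h Gaussian half-width on the dosage axis (default 0.1).
#' @param grid Window centres; default 100 points spanning `range(x)`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param interpretation `"sigma"` (default) or `"fwhm"`.
#' @param conf Interval coverage (default 0.95).
#' @return An object of class `window_stats`: data frame `grid` with
#'   columns `x` (centre), `mean_dosage`, `variance`, `lower`, `upper`,
#'   `flag`; plus the parameters.  Centres where the total weight
#'   underflows are flagged with missing values.
#' @export
gaussian_window_stats <- function(x, y, h = 0.1, grid = NULL, n_boot = 1000,
                                  seed = 1L,
                                  interpretation = c("sigma", "fwhm"),
                                  conf = 0.95) {
  interpretation <- match.arg(interpretation)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 10) stop("need at least 10 observations")
  sigma <- if (interpretation == "sigma") h else h / sqrt(2 * log(2))
  if (sigma <= 0) stop("half-width must be positive")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100)

  wstats <- function(xv, yv) {
    t(vapply(grid, function(x0) {
      w <- exp(-(xv - x0)^2 / (2 * sigma^2))
      sw <- sum(w)
      if (sw < .Machine$double.xmin) {
        return(c(NA_real_, NA_real_))
      }
      mx <- sum(w * xv) / sw
      my <- sum(w * yv) / sw
      c(mx, sum(w * (yv - my)^2) / sw)
    }, numeric(2)))
  }
  pt <- wstats(x, y)
  boots <- with_seed(seed, {
    matrix(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(x), replace = TRUE)
      wstats(x[idx], y[idx])[, 2]
    }, numeric(length(grid))), nrow = length(grid))
  })
  alpha <- (1 - conf) / 2
  lower <- apply(boots, 1, stats::quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(boots, 1, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  flag <- is.na(pt[, 1])
  structure(
    list(
      grid = data.frame(
        x = grid, mean_dosage = pt[, 1], variance = pt[, 2],
        lower = pmin(lower, pt[, 2]), upper = pmax(upper, pt[, 2]),
        flag = flag
      ),
      h = h, sigma = sigma, interpretation = interpretation,
      n_boot = n_boot, seed = seed, conf = conf, n = length(x)
    ),
    class = "window_stats"
  )
}

#' @export
print.window_stats <- function(x, ...) {
  pk <- x$grid[which.max(x$grid$variance), ]
  cat(sprintf(
    "<window_stats> Gaussian window sigma = %.3f on n = %d; variance peaks at dosage %.3f (var %.4g)\n",
    x$sigma, x$n, pk$mean_dosage, pk$variance
  ))
  invisible(x)
}

#' @export
plot.window_stats <- function(x, ...) {
  g <- x$grid[!x$grid$flag, ]
  graphics::plot(g$mean_dosage, g$variance, type = "n",
                 xlab = "Gaussian-weighted mean dosage",
                 ylab = "weighted phenotypic variance",
                 ylim = range(g$lower, g$upper), ...)
  graphics::polygon(c(g$mean_dosage, rev(g$mean_dosage)),
                    c(g$lower, rev(g$upper)), col = "grey85", border = NA)
  graphics::lines(g$mean_dosage, g$variance, lwd = 2)
  invisible(x)
}
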