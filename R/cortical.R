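#' Regional cortical mean membrane concentration
#'
#' Mean of the membrane amplitude `A(s)` over the arc of total length
#' `fraction` centred on the anterior (`s = 0`) or posterior (`s = 0.5`)
#' pole — by default the anterior-most or posterior-most 33% of the embryo
#' perimeter.  Flagged positions are excluded.
#'
#' @param profile A [fit_membrane_profiles()] result, or a numeric `A(s)`
#'   vector on a uniform `s` grid.
#' @param region `"anterior"` or `"posterior"`.
#' @param fraction Arc length as perimeter fraction (default 0.33;
#'   `fraction = 1` gives the global mean).
#' @param s Positions for a bare numeric profile.
#' @return The regional mean membrane concentration.
#' @export
cortical_mean <- function(profile, region = c("anterior", "posterior"),
                          fraction = 0.33, s = NULL) {
  region <- match.arg(region)
  if (inherits(profile, "membrane_profile")) {
    ok <- !profile$positions$flag
    A <- profile$positions$A[ok]
    s <- profile$positions$s[ok]
  } else {
    A <- as.numeric(profile)
    if (is.null(s)) s <- seq(0, 1 - 1 / length(A), by = 1 / length(A))
  }
  pole <- if (region == "anterior") 0 else 0.5
  dist <- abs(((s - pole + 0.5) %% 1) - 0.5)
  sel <- dist <= fraction / 2
  if (!any(sel)) stop("no unflagged positions inside the requested region")
  mean(A[sel])
}

#' Total dosage from whole-embryo mean intensity
#'
#' The mean pixel intensity within the embryo cross-section mask, divided
#' by the corresponding mean of the control cohort, so control embryos
#' score dosage ~1.  Apply after fluorescence correction.
#'
#' @param image An [embryo_image()].
#' @param mask Logical matrix: embryo cross-section ROI (e.g. the filled
#'   segmentation mask, eroded by 1 px).
#' @param control_mean Mean in-mask intensity of control embryos (> 0).
#' @param channel Channel role (default `"signal"`).
#' @param erode_px Pixels of mask erosion before measuring (default 1, a
#'   proxy for a manually drawn whole-cross-section ROI).
#' @return The dimensionless dosage.
#' @export
total_dosage <- function(image, mask, control_mean, channel = "signal",
                         erode_px = 1) {
  if (!is.numeric(control_mean) || control_mean <= 0) {
    stop("`control_mean` must be positive")
  }
  m <- get_channel(image, channel)
  stopifnot(all(dim(mask) == dim(m)))
  if (erode_px > 0) {
    kern <- EBImage::makeBrush(2 * erode_px + 1, shape = "diamond")
    mask <- as.matrix(EBImage::erode(EBImage::Image(mask * 1), kern)) > 0
  }
  if (!any(mask)) stop("empty embryo mask")
  mean(m[mask]) / control_mean
}

#' Mean in-mask intensity (helper for control cohorts)
#'
#' @param image An [embryo_image()].
#' @param mask Logical embryo mask.
#' @param channel Channel role.
#' @param erode_px Mask erosion in pixels (default 1).
#' @return Mean intensity inside the (eroded) mask.
#' @export
mask_mean <- function(image, mask, channel = "signal", erode_px = 1) {
  m <- get_channel(image, channel)
  if (erode_px > 0) {
    kern <- EBImage::makeBrush(2 * erode_px + 1, shape = "diamond")
    mask <- as.matrix(EBImage::erode(EBImage::Image(mask * 1), kern)) > 0
  }
  mean(m[mask])
}

#' Average membrane concentration profiles at selected dosage levels
#'
#' For each requested dosage level, selects the `k` embryos whose measured
#' dosage is closest to the level (ties broken by input order) and returns
#' the positionwise mean and SD of their membrane concentration profiles,
#' together with the selection.
#'
#' @param profiles Matrix (`n_embryos x n_positions`) of `A(s)` profiles on
#'   a common `s` grid, or a list of [fit_membrane_profiles()] results.
#' @param dosages Numeric vector of per-embryo dosages.
#' @param levels Dosage levels (default `c(1, 0.75, 0.5, 0.25)`).
#' @param k Number of embryos per level (default 7).
#' @return A list, one element per level: `level`, `selected` (row
#'   indices), `mean` and `sd` profiles.
#' @export
average_profiles_by_dosage <- function(profiles, dosages,
                                       levels = c(1, 0.75, 0.5, 0.25),
                                       k = 7) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    profiles <- do.call(rbind, lapply(profiles, function(p) p$positions$A))
  }
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != length(dosages)) {
    stop("`dosages` must have one value per profile row")
  }
  if (nrow(profiles) < k) {
    stop(sprintf("need at least k = %d embryos, have %d", k, nrow(profiles)))
  }
  lapply(levels, function(lv) {
    ord <- order(abs(dosages - lv)) # stable: ties keep input order
    sel <- ord[seq_len(k)]
    sub <- profiles[sel, , drop = FALSE]
    list(
      level = lv, selected = sel,
      mean = colMeans(sub),
      sd = if (k == 1) rep(0, ncol(sub)) else apply(sub, 2, stats::sd)
    )
  })
}
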