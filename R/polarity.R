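#' Composite PAR asymmetry index
#'
#' Signal-normalized asymmetry combining anterior (aPAR) and posterior
#' (pPAR) protein signals at the two poles:
#' `ASI = ((A_A - A_P) - (P_A - P_P)) / (A_A + A_P + P_A + P_P)`,
#' where `A_A`, `A_P` are aPAR concentrations at the anterior and posterior
#' poles and `P_A`, `P_P` the corresponding pPAR concentrations, each
#' normalized to the peak concentration achieved in wild-type embryos.
#' Perfect complementary polarity gives 1, any uniform state gives 0, and
#' inverted polarity gives negative values.
#'
#' @param A_A,A_P Anterior-protein concentration at the anterior and
#'   posterior pole.
#' @param P_A,P_P Posterior-protein concentration at the anterior and
#'   posterior pole.
#' @return The asymmetry index, in `[-1, 1]`.  Vectorized.
#' @export
asi_composite <- function(A_A, A_P, P_A, P_P) {
  den <- A_A + A_P + P_A + P_P
  if (any(den == 0)) stop("zero denominator: all four concentrations are 0")
  ((A_A - A_P) - (P_A - P_P)) / den
}

#' Single-protein asymmetry index from semicircle means
#'
#' `(A - P) / (A + P)` for anterior-enriched proteins (e.g. MEX-5) and
#' `(P - A) / (A + P)` for posterior-enriched ones (e.g. PAR-1), so that
#' correctly polarized embryos score positive; the sign is preserved, so
#' inverted polarity scores negative.
#'
#' @param anterior_mean,posterior_mean Mean intensities of the anterior and
#'   posterior semicircle (or pole-arc) ROIs.
#' @param protein_side `"anterior"` or `"posterior"`: the side on which the
#'   protein is normally enriched.
#' @return The asymmetry index.  Vectorized.
#' @export
asi_single <- function(anterior_mean, posterior_mean,
                       protein_side = c("anterior", "posterior")) {
  protein_side <- match.arg(protein_side)
  den <- anterior_mean + posterior_mean
  if (any(den <= 0)) stop("anterior + posterior mean must be positive")
  num <- anterior_mean - posterior_mean
  if (protein_side == "posterior") num <- -num
  num / den
}

#' Gradient magnitude (posterior minus anterior concentration)
#'
#' The absolute concentration difference between the posterior and anterior
#' ROI means, in intensity units, signed so that posterior enrichment is
#' positive.  Used e.g. for the PAR-1 cytoplasmic+membrane gradient
#' (delta-PAR-1 = P - A).
#'
#' @param posterior_mean,anterior_mean ROI mean intensities.
#' @return `posterior_mean - anterior_mean`.  Vectorized.
#' @export
gradient_magnitude <- function(posterior_mean, anterior_mean) {
  posterior_mean - anterior_mean
}

#' Locate the domain boundary as the half-max crossing of a membrane profile
#'
#' Scans the membrane concentration profile `A(s)` outward from the stated
#' pole (in both directions around the closed perimeter) and returns the
#' smallest arc distance at which the profile crosses
#' `(max(A) + min(A)) / 2`, with linear interpolation between samples.
#'
#' @param profile A [fit_membrane_profiles()] result, or a numeric vector of
#'   membrane amplitudes `A(s)`.
#' @param s Perimeter positions in `[0, 1)` (required when `profile` is a
#'   bare numeric vector; taken from the object otherwise).
#' @param from_pole `"anterior"` (pole at `s = 0`) or `"posterior"`
#'   (`s = 0.5`).
#' @return A list with `boundary` (arc distance from the pole as perimeter
#'   fraction, or `NA` if the profile never crosses half-max), `flag`
#'   (`"none"`, `"no_boundary"`, or `"multiple_crossings"`), and `half_max`.
#' @export
domain_boundary <- function(profile, s = NULL,
                            from_pole = c("anterior", "posterior")) {
  from_pole <- match.arg(from_pole)
  if (inherits(profile, "membrane_profile")) {
    ok <- !profile$positions$flag
    A <- profile$positions$A[ok]
    s <- profile$positions$s[ok]
  } else {
    A <- as.numeric(profile)
    if (is.null(s)) stop("`s` required for a bare numeric profile")
  }
  if (max(A) <= min(A)) {
    return(list(boundary = NA_real_, flag = "no_boundary",
                half_max = max(A)))
  }
  half <- (max(A) + min(A)) / 2
  pole <- if (from_pole == "anterior") 0 else 0.5
  # signed arc offset from the pole in (-0.5, 0.5]
  off <- ((s - pole + 0.5) %% 1) - 0.5
  o <- order(off)
  off <- off[o]
  A <- A[o]
  # close the circle: wrap ends so crossings spanning +/-0.5 are seen
  offc <- c(off, off[1] + 1)
  Ac <- c(A, A[1])
  above <- Ac >= half
  idx <- which(above[-1] != above[-length(above)])
  if (length(idx) == 0) {
    return(list(boundary = NA_real_, flag = "no_boundary", half_max = half))
  }
  cross <- offc[idx] + (half - Ac[idx]) / (Ac[idx + 1] - Ac[idx]) *
    (offc[idx + 1] - offc[idx])
  cross <- ((cross + 0.5) %% 1) - 0.5 # back to (-0.5, 0.5]
  dist <- abs(cross)
  flag <- if (length(dist) > 2) "multiple_crossings" else "none"
  list(boundary = min(dist), flag = flag, half_max = half)
}

#' Membrane:cytoplasm signal ratio from a perpendicular linescan
#'
#' Reproduces the domain-loading measurement: a short, `width_px`-wide
#' linescan is drawn perpendicular to the membrane (bisecting the domain,
#' inside to outside); the membrane signal is the best (maximum-mean)
#' contiguous `peak_px`-pixel window of the width-averaged profile, and the
#' cytoplasmic signal is the mean intensity of a caller-supplied interior
#' ROI excluding the nuclear/spindle area.
#'
#' @param image An [embryo_image()].
#' @param linescan List with `start` and `end`, each `c(row, col)` pixel
#'   coordinates of the line, and optionally `width_px` (default 10).
#' @param cytoplasm_roi Logical matrix (same size as the image) marking the
#'   interior ROI.
#' @param channel Channel role to measure (default `"signal"`).
#' @param peak_px Number of contiguous peak pixels averaged for the membrane
#'   value (default 5, approximating the membrane thickness).
#' @return A list with `ratio`, `membrane`, `cytoplasm`, and the sampled
#'   `profile`.
#' @export
mem_cyt_ratio <- function(image, linescan, cytoplasm_roi,
                          channel = "signal", peak_px = 5) {
  m <- get_channel(image, channel)
  stopifnot(all(dim(cytoplasm_roi) == dim(m)))
  cyt <- mean(m[cytoplasm_roi])
  if (!is.finite(cyt) || cyt <= 0) stop("cytoplasm ROI mean must be positive")
  width_px <- if (is.null(linescan$width_px)) 10 else linescan$width_px
  p0 <- as.numeric(linescan$start)
  p1 <- as.numeric(linescan$end)
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(peak_px + 1, ceiling(len) + 1)
  tt <- seq(0, 1, length.out = n)
  dirv <- (p1 - p0) / len
  perp <- c(-dirv[2], dirv[1])
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  prof <- vapply(tt, function(ti) {
    p <- p0 + ti * (p1 - p0)
    mean(bilinear_sample(m, p[1] + offs * perp[1], p[2] + offs * perp[2]),
         na.rm = TRUE)
  }, numeric(1))
  if (length(prof) < peak_px) stop("linescan shorter than the peak window")
  win <- stats::filter(prof, rep(1 / peak_px, peak_px), sides = 2)
  membrane <- max(win, na.rm = TRUE)
  list(ratio = membrane / cyt, membrane = membrane, cytoplasm = cyt,
       profile = prof)
}

#' Call PAR domains from a closed membrane:cytoplasm ratio trace
#'
#' Automated proxy for visual domain scoring: contiguous arcs of the closed
#' perimeter where the ratio trace exceeds `theta_high` (merged across the
#' `s = 0` wrap and filtered by a minimum arc length) are counted.  No arcs
#' with the trace maximum below `theta_low` scores `"no_domains"`; no arcs
#' but a maximum between the thresholds scores `"unclear"`; one arc is
#' `"monopolar"` and two or more arcs `"bipolar"`.
#'
#' @param ratio Numeric vector: membrane:cytoplasm ratio (or any cortical
#'   enrichment trace) on a closed perimeter grid.
#' @param s Perimeter positions in `[0, 1)` matching `ratio`; defaults to a
#'   uniform grid.
#' @param theta_high Arc-detection threshold (default 1.5).
#' @param theta_low Lower threshold separating `"no_domains"` from
#'   `"unclear"` (default 1.2).
#' @param min_arc Minimum arc length retained, as perimeter fraction
#'   (default 0.05).
#' @return An object of class `domain_call`: list with `category`, `arcs`
#'   (data frame: `s_start`, `s_end`, `length`, `mean_ratio`), and the
#'   thresholds used.
#' @export
detect_domains <- function(ratio, s = NULL, theta_high = 1.5,
                           theta_low = 1.2, min_arc = 0.05) {
  n <- length(ratio)
  if (n < 4) stop("ratio trace too short to be a closed perimeter")
  if (is.null(s)) s <- seq(0, 1 - 1 / n, by = 1 / n)
  if (is.unsorted(s) || any(s < 0) || any(s >= 1)) {
    stop("`s` must be sorted positions in [0, 1) (closed trace)")
  }
  above <- ratio > theta_high
  arcs <- data.frame(s_start = numeric(0), s_end = numeric(0),
                     length = numeric(0), mean_ratio = numeric(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge across the s = 0 wrap
    wrapped <- FALSE
    if (nrow(runs) > 1 && runs$start[1] == 1 && runs$end[nrow(runs)] == n) {
      runs$start[1] <- runs$start[nrow(runs)]
      runs <- runs[-nrow(runs), , drop = FALSE]
      wrapped <- TRUE
    }
    ds <- 1 / n
    for (i in seq_len(nrow(runs))) {
      idx <- if (runs$start[i] <= runs$end[i]) {
        runs$start[i]:runs$end[i]
      } else {
        c(runs$start[i]:n, 1:runs$end[i])
      }
      arc_len <- length(idx) * ds
      if (arc_len >= min_arc) {
        arcs <- rbind(arcs, data.frame(
          s_start = s[idx[1]], s_end = s[idx[length(idx)]],
          length = arc_len, mean_ratio = mean(ratio[idx])
        ))
      }
    }
    if (nrow(runs) == 1 && wrapped && nrow(arcs) == 1) {
      # fully-above trace is a single closed arc
      arcs$length <- min(arcs$length, 1)
    }
  }
  category <- if (nrow(arcs) == 0) {
    if (max(ratio) < theta_low) "no_domains" else "unclear"
  } else if (nrow(arcs) == 1) "monopolar" else "bipolar"
  structure(
    list(category = category, arcs = arcs,
         thresholds = list(theta_high = theta_high, theta_low = theta_low,
                           min_arc = min_arc)),
    class = "domain_call"
  )
}

#' @export
print.domain_call <- function(x, ...) {
  cat(sprintf("<domain_call> %s (%d arc%s)\n", x$category, nrow(x$arcs),
              if (nrow(x$arcs) == 1) "" else "s"))
  if (nrow(x$arcs) > 0) print(x$arcs, row.names = FALSE)
  invisible(x)
}
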