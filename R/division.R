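#' Spindle pole trajectory with event annotations
#'
#' Time series of anterior and posterior spindle pole (centrosome)
#' coordinates: `x` is the distance along the A-P axis from the anterior
#' pole of the embryo (um) and `y` the signed displacement off the central
#' A-P axis (um, `y = 0` on the axis).
#'
#' @param t Time in seconds, strictly increasing.
#' @param x_A,y_A,x_P,y_P Pole coordinates (um).
#' @param annotations Named list of event frame indices (e.g. `NEBD`,
#'   `prometaphase`, `anaphase_onset`, `telophase`).
#' @param frame_interval Frame interval in seconds.
#' @param embryo_length Embryo length in um (for normalized positions).
#' @return An object of class `spindle_track`.
#' @export
spindle_track <- function(t, x_A, y_A, x_P, y_P, annotations = list(),
                          frame_interval = NULL, embryo_length = NULL) {
  n <- length(t)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  stopifnot(length(x_A) == n, length(y_A) == n,
            length(x_P) == n, length(y_P) == n)
  bad <- vapply(annotations, function(f) f < 1 || f > n, logical(1))
  if (any(bad)) {
    stop(sprintf("annotation(s) outside track extent: %s",
                 paste(names(annotations)[bad], collapse = ", ")))
  }
  if (is.null(frame_interval)) frame_interval <- stats::median(diff(t))
  structure(
    list(frames = data.frame(t = t, x_A = x_A, y_A = y_A,
                             x_P = x_P, y_P = y_P),
         annotations = annotations,
         frame_interval = frame_interval,
         embryo_length = embryo_length),
    class = "spindle_track"
  )
}

#' @export
print.spindle_track <- function(x, ...) {
  cat(sprintf(
    "<spindle_track> %d frames @ %.3g s, events: %s\n",
    nrow(x$frames), x$frame_interval,
    if (length(x$annotations)) {
      paste(sprintf("%s=%d", names(x$annotations),
                    unlist(x$annotations)), collapse = ", ")
    } else "none"
  ))
  invisible(x)
}

#' Two-cell size asymmetry
#'
#' Area of the AB blastomere divided by the area of the whole embryo, both
#' measured on midplane masks.
#'
#' @param mask_AB Logical mask of the AB blastomere.
#' @param mask_whole Logical mask of the whole embryo; must contain
#'   `mask_AB`.
#' @return A list with `ab_fraction` and `flag` (`"degenerate"` when AB
#'   fills the whole embryo, `"none"` otherwise).
#' @export
size_asymmetry <- function(mask_AB, mask_whole) {
  stopifnot(all(dim(mask_AB) == dim(mask_whole)))
  if (!any(mask_whole)) stop("empty whole-embryo mask")
  if (any(mask_AB & !mask_whole)) {
    stop("AB mask extends outside the whole-embryo mask")
  }
  f <- sum(mask_AB) / sum(mask_whole)
  list(ab_fraction = f, flag = if (f >= 1) "degenerate" else "none")
}

#' Division asynchrony between AB and P1
#'
#' The lag between furrow ingression of the two blastomeres,
#' `delta_t = t_P1 - t_AB` (seconds); positive in wild type, where AB
#' divides first (~2 min ahead of P1).
#'
#' @param t_AB,t_P1 Furrow ingression times (s) on the same clock.
#' @return A list with `asynchrony_s` and `flag` (`"inverted"` when P1
#'   divides first).
#' @export
division_asynchrony <- function(t_AB, t_P1) {
  if (is.na(t_AB) || is.na(t_P1)) stop("both event times are required")
  dt <- t_P1 - t_AB
  list(asynchrony_s = dt, flag = if (dt < 0) "inverted" else "none")
}

#' Transverse spindle oscillation magnitude
#'
#' Population standard deviation of the off-axis pole displacement `y`
#' over the annotated mitotic window (late prometaphase through telophase
#' by default), per pole.
#'
#' @param track A [spindle_track()].
#' @param window Character pair of annotation names, or integer pair of
#'   frame indices, delimiting the window (inclusive).
#' @return Named numeric: `sigma_A`, `sigma_P` (um).
#' @export
oscillation_magnitude <- function(track,
                                  window = c("prometaphase", "telophase")) {
  stopifnot(inherits(track, "spindle_track"))
  w <- resolve_window(track, window)
  if (diff(w) + 1 < 5) stop("need at least 5 frames in the window")
  idx <- w[1]:w[2]
  popsd <- function(v) sqrt(mean((v - mean(v))^2))
  c(sigma_A = popsd(track$frames$y_A[idx]),
    sigma_P = popsd(track$frames$y_P[idx]))
}

resolve_window <- function(track, window) {
  n <- nrow(track$frames)
  w <- vapply(window, function(el) {
    if (is.character(el)) {
      if (is.null(track$annotations[[el]])) {
        stop(sprintf("annotation '%s' missing from track", el))
      }
      track$annotations[[el]]
    } else {
      as.integer(el)
    }
  }, numeric(1))
  w <- as.integer(w)
  if (any(w < 1 | w > n) || w[2] < w[1]) stop("window outside track extent")
  w
}

#' Final spindle pole positions as fraction of embryo length
#'
#' Pole positions `x` at the telophase frame, divided by the embryo length.
#'
#' @param track A [spindle_track()] with a `telophase` annotation and
#'   `embryo_length` set.
#' @return Named numeric: `x_A`, `x_P` (fractions of embryo length).
#' @export
final_pole_positions <- function(track) {
  stopifnot(inherits(track, "spindle_track"))
  if (is.null(track$annotations$telophase)) {
    stop("track has no telophase annotation")
  }
  if (is.null(track$embryo_length) || !is.finite(track$embryo_length)) {
    stop("embryo_length is required to normalize pole positions")
  }
  i <- track$annotations$telophase
  c(x_A = track$frames$x_A[i] / track$embryo_length,
    x_P = track$frames$x_P[i] / track$embryo_length)
}

#' Maximum pole velocity after spindle severing
#'
#' Pole tracks (`x`, `y`) are smoothed with a moving average over
#' `smooth_frames` frames, Euclidean displacements are measured over every
#' rolling window of duration `window_s`, and the maximum displacement per
#' window duration gives the maximum outward velocity per pole; the
#' posterior-minus-anterior difference reports the cortical pulling-force
#' imbalance.
#'
#' @param track A [spindle_track()] (post-ablation acquisition, typically
#'   ~10 frames/s).
#' @param smooth_frames Moving-average span in frames (default 10, i.e. 1 s
#'   at 10 fps).
#' @param window_s Rolling displacement window in seconds (default 1).
#' @return A list with `v_max` (named: `A`, `P`, um/s) and `delta_v`
#'   (`v_max[P] - v_max[A]`).
#' @export
severing_max_velocity <- function(track, smooth_frames = 10, window_s = 1.0) {
  stopifnot(inherits(track, "spindle_track"))
  dt <- track$frame_interval
  wf <- max(1L, as.integer(round(window_s / dt)))
  n <- nrow(track$frames)
  if (n < smooth_frames + wf) {
    stop(sprintf("track too short: need >= %d frames, have %d",
                 smooth_frames + wf, n))
  }
  smooth <- function(v) {
    if (smooth_frames <= 1) return(v)
    sm <- stats::filter(v, rep(1 / smooth_frames, smooth_frames), sides = 2)
    as.numeric(sm)
  }
  vmax_pole <- function(x, y) {
    xs <- smooth(x)
    ys <- smooth(y)
    ok <- which(!is.na(xs))
    xs <- xs[ok]
    ys <- ys[ok]
    m <- length(xs) - wf
    if (m < 1) stop("track too short after smoothing for the rolling window")
    i <- seq_len(m)
    disp <- sqrt((xs[i + wf] - xs[i])^2 + (ys[i + wf] - ys[i])^2)
    max(disp) / (wf * dt)
  }
  vA <- vmax_pole(track$frames$x_A, track$frames$y_A)
  vP <- vmax_pole(track$frames$x_P, track$frames$y_P)
  list(v_max = c(A = vA, P = vP), delta_v = vP - vA)
}
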