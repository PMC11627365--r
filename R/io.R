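# Fixed affine map used when storing float intensities in TIFF pages,
# which hold values in [0, 1]: stored = (value + offset) / scale.  The
# offset leaves headroom for negative values (noise around zero background,
# uncorrected baselines).
TIFF_INTENSITY_SCALE <- 66559
TIFF_INTENSITY_OFFSET <- 1024

#' Write an embryo image as a multi-page TIFF
#'
#' One 32-bit float page per channel.  Intensities are divided by a fixed
#' scale (65535) for storage; channel roles, the pixel size and the scale
#' are recorded in a JSON sidecar (`<path>.json`) so the image round-trips
#' losslessly through [read_embryo_tiff()].
#'
#' @param image An [embryo_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_embryo_tiff <- function(image, path) {
  stopifnot(inherits(image, "embryo_image"))
  pages <- lapply(image$channels, function(m) {
    (m + TIFF_INTENSITY_OFFSET) / TIFF_INTENSITY_SCALE
  })
  if (any(vapply(pages, function(p) any(p < 0) || any(p > 1), logical(1)))) {
    stop(sprintf("intensities outside the storable range [%d, %d]",
                 -TIFF_INTENSITY_OFFSET,
                 TIFF_INTENSITY_SCALE - TIFF_INTENSITY_OFFSET))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(roles = names(image$channels), pixel_size = image$pixel_size,
         scale = TIFF_INTENSITY_SCALE, offset = TIFF_INTENSITY_OFFSET),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multi-page TIFF as an embryo image
#'
#' @param path TIFF path written by [write_embryo_tiff()] (or any
#'   multi-page TIFF; then `roles` and `pixel_size` must be given).
#' @param roles Channel role names, one per page; defaults to the sidecar.
#' @param pixel_size Pixel scale um/px; defaults to the sidecar.
#' @return An [embryo_image()].
#' @export
read_embryo_tiff <- function(path, roles = NULL, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- TIFF_INTENSITY_SCALE
  offset <- TIFF_INTENSITY_OFFSET
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(roles)) roles <- meta$roles
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$offset)) offset <- meta$offset
  }
  if (is.null(roles) || length(roles) != length(pages)) {
    stop("channel roles missing or not matching the page count")
  }
  if (is.null(pixel_size)) stop("pixel_size missing (no sidecar)")
  channels <- lapply(pages, function(p) p * scale - offset)
  names(channels) <- roles
  embryo_image(channels, pixel_size)
}

# Full-precision CSV writers: numeric columns are serialized with %.17g so
# that write -> read round trips are exact and reruns are byte-identical.
write_table_precise <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a cohort table
#'
#' Cohort tables have one row per embryo (id, condition, dosage, phenotype
#' and metric columns, flags).  Numeric columns are stored at full float
#' precision so the round trip is lossless.
#'
#' @param cohort Data frame.
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  write_table_precise(cohort, path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read spindle tracks as long-format CSV
#'
#' Schema: `embryo_id, pole (A|P), frame, t_s, x_um, y_um`; annotations go
#' in a companion events CSV with schema `embryo_id, event, frame`.
#'
#' @param tracks Named list of [spindle_track()]s (names = embryo ids).
#' @param path CSV path.
#' @return `path` invisibly (write); for the reader, a named list of
#'   `spindle_track`s (annotations filled from `events_path` if given).
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(names(tracks), function(id) {
    fr <- tracks[[id]]$frames
    n <- nrow(fr)
    rbind(
      data.frame(embryo_id = id, pole = "A", frame = seq_len(n),
                 t_s = fr$t, x_um = fr$x_A, y_um = fr$y_A),
      data.frame(embryo_id = id, pole = "P", frame = seq_len(n),
                 t_s = fr$t, x_um = fr$x_P, y_um = fr$y_P)
    )
  })
  write_table_precise(do.call(rbind, rows), path)
}

#' @rdname write_tracks_csv
#' @param events_path Optional events CSV (`embryo_id, event, frame`).
#' @param embryo_length Optional named vector of embryo lengths (um).
#' @export
read_tracks_csv <- function(path, events_path = NULL, embryo_length = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "pole", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("track CSV missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  ev <- NULL
  if (!is.null(events_path)) {
    ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
    ev_need <- c("embryo_id", "event", "frame")
    ev_miss <- setdiff(ev_need, names(ev))
    if (length(ev_miss)) {
      stop(sprintf("events CSV missing column(s): %s",
                   paste(ev_miss, collapse = ", ")))
    }
  }
  ids <- unique(df$embryo_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$embryo_id == id, ]
    A <- sub[sub$pole == "A", ][order(sub$frame[sub$pole == "A"]), ]
    P <- sub[sub$pole == "P", ][order(sub$frame[sub$pole == "P"]), ]
    ann <- list()
    if (!is.null(ev)) {
      se <- ev[ev$embryo_id == id, ]
      ann <- stats::setNames(as.list(as.integer(se$frame)), se$event)
    }
    len <- if (!is.null(embryo_length)) embryo_length[[as.character(id)]] else NULL
    spindle_track(A$t_s, A$x_um, A$y_um, P$x_um, P$y_um,
                  annotations = ann, embryo_length = len)
  })
  stats::setNames(out, ids)
}

#' Write a membrane profile as CSV
#'
#' Columns `s, A, C, c, rss, flag`; the global fit parameters are appended
#' as constant columns (`w_gauss`, `w_erf`, `offset`) so the file stays a
#' plain rectangular CSV.
#'
#' @param profile A [fit_membrane_profiles()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "membrane_profile"))
  df <- profile$positions
  df$w_gauss <- profile$w_gauss
  df$w_erf <- profile$w_erf
  df$offset <- profile$offset
  write_table_precise(df, path)
}

#' Write a boundary contour as CSV (columns `s, row, col, n_row, n_col`)
#'
#' @param contour A [segment_embryo()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "boundary_contour"))
  write_table_precise(contour$points, path)
}

#' Serialize a ground-truth record to JSON
#'
#' Large rasters (pure-signal channels, masks) are dropped; everything
#' needed to recompute true metrics (spec parameters, sampled true
#' profiles, true ASI/boundaries/means) is kept.
#'
#' @param truth The `truth` element of [render_embryo()] (or any list).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  keep <- truth[setdiff(names(truth),
                        c("mask_true", "pure_signal", "af_pure"))]
  keep$spec <- unclass(keep$spec)
  keep$spec$membrane <- lapply(keep$spec$membrane, unclass)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
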