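#' Multi-channel midplane embryo image
#'
#' Container for a single-embryo midplane fluorescence snapshot: one numeric
#' matrix per channel (rows are image rows, top-left origin) plus the pixel
#' scale.  Channels are addressed by *role* (e.g. `"signal"`, `"af"`,
#' `"apar"`, `"ppar"`), mirroring how acquisition channels map onto
#' fluorophores and the red-shifted autofluorescence channel.
#'
#' @param channels Named list of numeric matrices, all the same dimension.
#'   Names are the channel roles.
#' @param pixel_size Pixel scale in micrometres per pixel.
#' @return An object of class `embryo_image`.
#' @export
embryo_image <- function(channels, pixel_size) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1)))) {
    stop("every channel must be a numeric matrix")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all channels must share the same dimensions")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size),
    class = "embryo_image"
  )
}

#' @export
print.embryo_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<embryo_image> %d x %d px (%.3f um/px), channels: %s\n",
    d[1], d[2], x$pixel_size, paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Extract one channel from an embryo image
#'
#' @param image An [embryo_image()].
#' @param role Channel role name.
#' @return The channel matrix.
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "embryo_image"))
  if (!role %in% names(image$channels)) {
    stop(sprintf(
      "channel role '%s' not present (have: %s)",
      role, paste(names(image$channels), collapse = ", ")
    ))
  }
  image$channels[[role]]
}

# Error function, in terms of the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Bicubic (Catmull-Rom, a = -0.5) interpolation of matrix `m` at
# fractional (row, col) positions.  Interpolating kernel: attenuates thin
# ridges far less than bilinear.  Out-of-bounds (incl. the 1-px border
# needed by the 4x4 stencil) returns NA.
bicubic_sample <- function(m, row, col) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- rep(NA_real_, length(row))
  ok <- row >= 2 & row <= nr - 1 & col >= 2 & col <= nc - 1 &
    is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]
  cc <- col[ok]
  r0 <- pmin(pmax(floor(r), 2), nr - 2)
  c0 <- pmin(pmax(floor(cc), 2), nc - 2)
  fr <- r - r0
  fc <- cc - c0
  kern <- function(t) {
    at <- abs(t)
    ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
           ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
  }
  v <- 0
  for (i in -1:2) {
    wri <- kern(fr - i)
    for (j in -1:2) {
      wcj <- kern(fc - j)
      v <- v + wri * wcj * m[(c0 + j - 1) * nr + r0 + i]
    }
  }
  out[ok] <- v
  out
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Positions are in pixel-centre coordinates (pixel (1,1) centred at 1,1).
# Out-of-bounds queries return NA.
bilinear_sample <- function(m, row, col) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- rep(NA_real_, length(row))
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc & is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]
  cc <- col[ok]
  r0 <- pmin(pmax(floor(r), 1), nr - 1)
  c0 <- pmin(pmax(floor(cc), 1), nc - 1)
  fr <- r - r0
  fc <- cc - c0
  i00 <- (c0 - 1) * nr + r0
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + nr] +
    fr * fc * m[i00 + nr + 1]
  out[ok] <- v
  out
}
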