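#' Fit a spectral autofluorescence (SAIBR-style) correction model
#'
#' Autofluorescence excited at 488 nm has a much wider emission spectrum
#' than GFP, so its level can be gauged from a parallel red-shifted channel
#' and regressed out.  This fits the least-squares line
#' `signal = m * AF + b` on GFP-negative control embryos, either pooling
#' in-mask pixels (`mode = "pixel"`) or using per-embryo in-mask means
#' (`mode = "embryo"`).
#'
#' @param controls List of [embryo_image()]s of unlabeled control embryos,
#'   each with the signal channel and an `"af"` channel.
#' @param masks List of logical embryo masks matching `controls`.
#' @param mode `"pixel"` or `"embryo"`.
#' @param signal_channel,af_channel Channel roles (defaults `"signal"`,
#'   `"af"`).
#' @param max_pixels Pixel mode subsamples at most this many in-mask pixels
#'   by a deterministic fixed stride (default `1e5`).
#' @return An object of class `af_model`: list with `slope`, `intercept`,
#'   `mode`, and `diagnostics` (`n_embryos`, `n_points`, `residual_sd`).
#' @export
fit_af_model <- function(controls, masks, mode = c("pixel", "embryo"),
                         signal_channel = "signal", af_channel = "af",
                         max_pixels = 1e5) {
  mode <- match.arg(mode)
  if (length(controls) < 1) stop("need at least one control embryo")
  if (length(masks) != length(controls)) {
    stop("`masks` must match `controls`")
  }
  if (mode == "pixel") {
    af <- unlist(lapply(seq_along(controls), function(i) {
      get_channel(controls[[i]], af_channel)[masks[[i]]]
    }))
    sig <- unlist(lapply(seq_along(controls), function(i) {
      get_channel(controls[[i]], signal_channel)[masks[[i]]]
    }))
    if (length(af) > max_pixels) {
      stride <- ceiling(length(af) / max_pixels)
      keep <- seq(1, length(af), by = stride)
      af <- af[keep]
      sig <- sig[keep]
    }
  } else {
    if (length(controls) < 2) stop("embryo mode needs >= 2 control embryos")
    af <- vapply(seq_along(controls), function(i) {
      mean(get_channel(controls[[i]], af_channel)[masks[[i]]])
    }, numeric(1))
    sig <- vapply(seq_along(controls), function(i) {
      mean(get_channel(controls[[i]], signal_channel)[masks[[i]]])
    }, numeric(1))
  }
  if (stats::var(af) < .Machine$double.eps * max(1, mean(af)^2)) {
    stop("degenerate fit: autofluorescence channel has zero variance")
  }
  fit <- stats::lm.fit(cbind(1, af), sig)
  structure(
    list(
      slope = unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      mode = mode,
      diagnostics = list(
        n_embryos = length(controls),
        n_points = length(af),
        residual_sd = stats::sd(fit$residuals)
      )
    ),
    class = "af_model"
  )
}

#' @export
print.af_model <- function(x, ...) {
  cat(sprintf(
    "<af_model> signal = %.4f * AF + %.4f  (%s mode, %d embryos, %d points, resid SD %.3f)\n",
    x$slope, x$intercept, x$mode, x$diagnostics$n_embryos,
    x$diagnostics$n_points, x$diagnostics$residual_sd
  ))
  invisible(x)
}

#' Apply spectral autofluorescence correction to an image
#'
#' Subtracts the inferred autofluorescence `m * AF + b` from the signal
#' channel: pixel-by-pixel (spatial correction) or embryo-by-embryo (a
#' scalar based on the in-mask AF mean).  Corrected values may be negative
#' and are deliberately not clipped, since clipping would bias means.
#'
#' @param image An [embryo_image()].
#' @param model An [fit_af_model()] result.
#' @param mode `"pixel"` or `"embryo"`.
#' @param mask Logical embryo mask (required for `"embryo"` mode).
#' @param signal_channel,af_channel Channel roles.
#' @return The corrected [embryo_image()], with a `correction` attribute
#'   recording the model used.
#' @export
correct_image <- function(image, model, mode = c("pixel", "embryo"),
                          mask = NULL, signal_channel = "signal",
                          af_channel = "af") {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "af_model"))
  sig <- get_channel(image, signal_channel)
  af <- get_channel(image, af_channel)
  if (!all(dim(sig) == dim(af))) stop("channel shape mismatch")
  corrected <- if (mode == "pixel") {
    sig - (model$slope * af + model$intercept)
  } else {
    if (is.null(mask)) stop("embryo mode requires `mask`")
    sig - (model$slope * mean(af[mask]) + model$intercept)
  }
  image$channels[[signal_channel]] <- corrected
  attr(image, "correction") <- list(
    type = "saibr", mode = mode, slope = model$slope,
    intercept = model$intercept, channel = signal_channel
  )
  image
}

#' Flat background measured on unlabeled embryos
#'
#' Mean in-mask background level of a channel across a sample of unlabeled
#' embryos, for fluorophore/filter configurations (mNG, mCherry) where
#' autofluorescence is minimal and a scalar subtraction suffices.
#'
#' @param controls List of unlabeled [embryo_image()]s.
#' @param masks List of logical embryo masks.
#' @param channel Channel role.
#' @return An object of class `flat_background`: list with `level` and
#'   `n_embryos`.
#' @export
measure_flat_background <- function(controls, masks, channel = "signal") {
  if (length(controls) < 1) stop("need at least one control embryo")
  vals <- vapply(seq_along(controls), function(i) {
    mean(get_channel(controls[[i]], channel)[masks[[i]]])
  }, numeric(1))
  structure(
    list(level = mean(vals), n_embryos = length(controls), channel = channel),
    class = "flat_background"
  )
}

#' Subtract a flat background level from a channel
#'
#' @param image An [embryo_image()].
#' @param bg A [measure_flat_background()] result, or a scalar level.
#' @param channel Channel role (defaults to the channel recorded in `bg`,
#'   or `"signal"`).
#' @return The corrected [embryo_image()] with a `correction` attribute.
#' @export
subtract_flat_background <- function(image, bg, channel = NULL) {
  level <- if (inherits(bg, "flat_background")) bg$level else as.numeric(bg)
  if (is.null(channel)) {
    channel <- if (inherits(bg, "flat_background")) bg$channel else "signal"
  }
  m <- get_channel(image, channel)
  image$channels[[channel]] <- m - level
  attr(image, "correction") <- list(type = "flat", level = level,
                                    channel = channel)
  image
}
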