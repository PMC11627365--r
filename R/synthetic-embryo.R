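#' Membrane concentration model along the embryo perimeter
#'
#' Describes the true cortical concentration profile of one protein as two
#' plateaus (anterior and posterior) joined by logistic transitions in the
#' perimeter coordinate.  With `t` the circular arc distance from the anterior
#' pole (perimeter fraction, in `[0, 0.5]`), the profile is
#' `A(t) = m_post + (m_ant - m_post) * plogis(sharpness * (boundary - t))`,
#' so `boundary` is the half-max domain boundary position measured from the
#' anterior pole and `sharpness` controls the transition width.
#'
#' @param m_ant,m_post Anterior and posterior plateau concentrations
#'   (arbitrary intensity units, `>= 0`).
#' @param boundary Domain boundary position as perimeter fraction from the
#'   anterior pole, in `[0, 0.5]`.
#' @param sharpness Logistic steepness in units of inverse perimeter fraction.
#' @return An object of class `membrane_model`.
#' @export
membrane_model <- function(m_ant, m_post, boundary = 0.25, sharpness = 20) {
  if (m_ant < 0 || m_post < 0) stop("plateau levels must be >= 0")
  if (boundary < 0 || boundary > 0.5) stop("`boundary` must lie in [0, 0.5]")
  if (sharpness <= 0) stop("`sharpness` must be positive")
  structure(
    list(m_ant = m_ant, m_post = m_post, boundary = boundary,
         sharpness = sharpness),
    class = "membrane_model"
  )
}

# Evaluate a membrane model at perimeter positions s in [0, 1)
# (s = 0 anterior pole; profile symmetric about the long axis).
eval_membrane_model <- function(model, s) {
  t <- pmin(s %% 1, 1 - (s %% 1)) # circular distance from anterior pole
  model$m_post + (model$m_ant - model$m_post) *
    stats::plogis(model$sharpness * (model$boundary - t))
}

#' Specification of a synthetic midplane embryo image
#'
#' Defines the forward model from which [render_embryo()] draws an image:
#' an elliptical midplane cross-section whose cross-membrane intensity
#' profile at perimeter position `s` is a Gaussian membrane ridge of
#' amplitude `A(s)` on top of an error-function cytoplasmic step of height
#' `cytoplasm`, plus a spectrally distinct autofluorescence component that
#' bleeds into the signal channel, a camera offset, and additive Gaussian
#' noise.
#'
#' @param semi_axes Ellipse semi-axes `c(a, b)` in micrometres, `a > b > 0`
#'   (long axis horizontal; anterior pole on the left).
#' @param pixel_size Pixel scale, um/px.  The default 0.256 um/px matches a
#'   50-pixel straightening width of 12.8 um.
#' @param membrane A [membrane_model()], or a named list of them (one signal
#'   channel per element, e.g. `list(apar = ..., ppar = ...)`).  A single
#'   unnamed model is rendered as channel role `"signal"`.
#' @param cytoplasm Cytoplasmic plateau intensity (units, `>= 0`).
#' @param ridge_width Gaussian cross-section SD of the membrane ridge, um
#'   (PSF-like; also used as the error-function edge width).
#' @param af_params Autofluorescence component: list with `af_mean`
#'   (interior AF level), `af_gradient` (additive linear tilt along the A-P
#'   axis, total change across the embryo length) and `bleed_factor`
#'   (fraction of AF appearing in each signal channel).
#' @param offset Camera baseline added to signal channels (units).
#' @param noise_sd Additive Gaussian noise SD per pixel (units, `>= 0`).
#' @param seed Integer RNG seed; identical specs with identical seeds render
#'   bit-identical images.
#' @param canvas_px Optional `c(nrow, ncol)` canvas override.  Must leave at
#'   least a 10% margin around the ellipse.
#' @param margin_um Canvas margin around the ellipse, um.  The default
#'   (`max(0.1 * a, 3 * ridge_width + 1, 8)`) leaves room for the standard
#'   50-pixel (12.8 um) straightening window to stay inside the image.
#' @return An object of class `embryo_spec`.
#' @export
embryo_spec <- function(semi_axes = c(25, 15),
                        pixel_size = 0.256,
                        membrane = membrane_model(100, 100),
                        cytoplasm = 30,
                        ridge_width = 0.5,
                        af_params = list(af_mean = 0, af_gradient = 0,
                                         bleed_factor = 0),
                        offset = 0,
                        noise_sd = 0,
                        seed = 1L,
                        canvas_px = NULL,
                        margin_um = NULL) {
  a <- semi_axes[1]
  b <- semi_axes[2]
  if (!(a > b && b > 0)) stop("require semi_axes a > b > 0")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  if (cytoplasm < 0) stop("`cytoplasm` must be >= 0")
  if (ridge_width <= 0) stop("`ridge_width` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (inherits(membrane, "membrane_model")) membrane <- list(signal = membrane)
  if (!all(vapply(membrane, inherits, logical(1), "membrane_model"))) {
    stop("`membrane` must be a membrane_model or a named list of them")
  }
  if (is.null(names(membrane)) || any(!nzchar(names(membrane)))) {
    stop("multiple membrane models must be named by channel role")
  }
  af <- utils::modifyList(
    list(af_mean = 0, af_gradient = 0, bleed_factor = 0), af_params
  )
  spec <- structure(
    list(semi_axes = c(a, b), pixel_size = pixel_size, membrane = membrane,
         cytoplasm = cytoplasm, ridge_width = ridge_width, af_params = af,
         offset = offset, noise_sd = noise_sd, seed = as.integer(seed),
         canvas_px = canvas_px),
    class = "embryo_spec"
  )
  # canvas sizing (10% margin minimum, ridge support, straightening window)
  margin <- if (is.null(margin_um)) {
    max(0.1 * a, 3 * ridge_width + 1, 8)
  } else {
    margin_um
  }
  auto <- c(2 * ceiling((b + margin) / pixel_size),
            2 * ceiling((a + margin) / pixel_size))
  if (is.null(canvas_px)) {
    spec$canvas_px <- auto
  } else {
    if (canvas_px[1] * pixel_size < 2 * (b + 0.1 * a) ||
        canvas_px[2] * pixel_size < 2 * (a + 0.1 * a)) {
      stop("`canvas_px` too small: ellipse plus 10% margin does not fit")
    }
    spec$canvas_px <- canvas_px
  }
  spec
}

# Arc-length lookup for an ellipse (a cos th, b sin th).  Returns a function
# mapping th to perimeter fraction s, with s = 0 at the anterior pole
# (th = pi) and s increasing with th (counterclockwise), plus the perimeter.
ellipse_arclength <- function(a, b, n = 4096) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  sp <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
  L <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(th)))
  P <- L[length(L)]
  L_at_pi <- stats::approx(th, L, xout = pi)$y
  list(
    s_of_theta = function(theta) {
      theta <- theta %% (2 * pi)
      Lv <- stats::approx(th, L, xout = theta)$y
      ((Lv - L_at_pi) / P) %% 1
    },
    perimeter = P
  )
}

# Signed distance (positive outside) and perimeter position of the nearest
# boundary point, for query points (x, y) relative to the ellipse centre.
ellipse_signed_distance <- function(x, y, a, b, arc = NULL) {
  th <- atan2(y / b, x / a)
  for (i in 1:15) {
    sth <- sin(th); cth <- cos(th)
    dx <- x - a * cth
    dy <- y - b * sth
    g <- -dx * a * sth + dy * b * cth
    gp <- -(a^2 * sth^2 + b^2 * cth^2) - dx * a * cth - dy * b * sth
    th <- th - g / gp
  }
  sth <- sin(th); cth <- cos(th)
  d <- sqrt((x - a * cth)^2 + (y - b * sth)^2)
  rho <- sqrt((x / a)^2 + (y / b)^2)
  d <- d * ifelse(rho >= 1, 1, -1)
  if (is.null(arc)) arc <- ellipse_arclength(a, b)
  list(d = d, s = arc$s_of_theta(th))
}

#' Render a synthetic embryo image with ground truth
#'
#' Draws the forward model defined by an [embryo_spec()] onto a pixel grid:
#' for each pixel, the signed distance `d` to the ellipse boundary (negative
#' inside) and the perimeter position `s` of the nearest boundary point are
#' computed, and each signal channel takes the value
#' `A(s) * exp(-d^2 / (2 w^2)) + (C / 2) * (1 + erf(-d / (w * sqrt(2))))`
#' plus AF bleed-through, camera offset and noise.  A separate `"af"`
#' channel carries the autofluorescence component with independent noise.
#'
#' @param spec An [embryo_spec()].
#' @return A list with elements `image` (an [embryo_image()]) and `truth`
#'   (ground-truth record: the spec, true membrane profiles `A(s)` sampled
#'   on a fixed `s` grid, cytoplasm level, interior mask, noise-free pure
#'   signal channels, per-channel interior means, true domain boundaries,
#'   and — for two-protein apar/ppar renders — the true composite asymmetry
#'   index over 33% pole arcs).
#' @export
render_embryo <- function(spec) {
  stopifnot(inherits(spec, "embryo_spec"))
  a <- spec$semi_axes[1]
  b <- spec$semi_axes[2]
  px <- spec$pixel_size
  nr <- spec$canvas_px[1]
  nc <- spec$canvas_px[2]
  w <- spec$ridge_width

  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  x <- (col - (nc + 1) / 2) * px
  y <- ((nr + 1) / 2 - row) * px

  arc <- ellipse_arclength(a, b)
  ed <- ellipse_signed_distance(as.vector(x), as.vector(y), a, b, arc)
  d <- matrix(ed$d, nr, nc)
  s <- matrix(ed$s, nr, nc)

  gauss <- exp(-d^2 / (2 * w^2))
  step <- 0.5 * (1 + erf(-d / (w * sqrt(2))))

  # autofluorescence: interior fill with linear A-P tilt
  afp <- spec$af_params
  xfrac <- pmin(pmax((x + a) / (2 * a), 0), 1)
  af_pure <- (afp$af_mean + afp$af_gradient * (xfrac - 0.5)) * step

  pure <- lapply(spec$membrane, function(mm) {
    eval_membrane_model(mm, s) * gauss + spec$cytoplasm * step
  })

  channels <- with_seed(spec$seed, {
    ch <- lapply(pure, function(p) {
      v <- p + afp$bleed_factor * af_pure + spec$offset
      if (spec$noise_sd > 0) v <- v + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
      v
    })
    afv <- af_pure
    if (spec$noise_sd > 0) {
      afv <- afv + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    ch$af <- afv
    ch
  })

  mask_true <- d < 0
  s_grid <- seq(0, 1 - 1 / 1024, by = 1 / 1024)
  A_true <- lapply(spec$membrane, eval_membrane_model, s = s_grid)
  mean_interior <- vapply(pure, function(p) mean(p[mask_true]), numeric(1))

  truth <- list(
    spec = spec,
    s_grid = s_grid,
    A_true = A_true,
    cytoplasm = spec$cytoplasm,
    mask_true = mask_true,
    pure_signal = pure,
    af_pure = af_pure,
    mean_interior = mean_interior,
    boundary_true = vapply(spec$membrane, function(mm) mm$boundary, numeric(1)),
    perimeter_um = arc$perimeter
  )
  polarized <- all(c("apar", "ppar") %in% names(spec$membrane)) &&
    all(vapply(spec$membrane[c("apar", "ppar")],
               function(mm) max(mm$m_ant, mm$m_post) > 0, logical(1)))
  if (polarized) {
    truth$asi_true <- true_composite_asi(spec, fraction = 0.33)
  }
  list(image = embryo_image(channels, px), truth = truth)
}

# Arc means of a membrane model over the anterior / posterior `fraction`
# arcs (the estimand that cortical_mean() measures), on a dense grid.
true_arc_means <- function(model, fraction = 0.33, n = 4096) {
  s <- seq(0, 1 - 1 / n, by = 1 / n)
  A <- eval_membrane_model(model, s)
  t <- pmin(s, 1 - s)
  c(anterior = mean(A[t <= fraction / 2]),
    posterior = mean(A[abs(s - 0.5) <= fraction / 2]))
}

# True composite ASI of a two-protein (apar/ppar) spec, using fraction-arc
# pole means normalized to each protein's peak concentration.
true_composite_asi <- function(spec, fraction = 0.33) {
  am <- true_arc_means(spec$membrane$apar, fraction)
  pm <- true_arc_means(spec$membrane$ppar, fraction)
  s <- seq(0, 1 - 1 / 4096, by = 1 / 4096)
  pk_a <- max(eval_membrane_model(spec$membrane$apar, s))
  pk_p <- max(eval_membrane_model(spec$membrane$ppar, s))
  as.numeric(asi_composite(am[["anterior"]] / pk_a, am[["posterior"]] / pk_a,
                           pm[["anterior"]] / pk_p, pm[["posterior"]] / pk_p))
}

#' Build a two-protein embryo spec with a prescribed true asymmetry index
#'
#' Constructs complementary anterior (apar) and posterior (ppar) membrane
#' models whose true composite asymmetry index — computed from 33% pole-arc
#' means exactly as the measurement pipeline defines it — equals
#' `target_asi`.  The two proteins share a peak level `M` and mix toward a
#' uniform profile: `A(s) = M * (u + (1 - u) * f(s))` for the anterior
#' protein and the mirror image for the posterior one, with the blend `u`
#' solved from the target.
#'
#' @param target_asi Desired true composite ASI in `[0, 1)`.
#' @param M Peak plateau concentration (units).
#' @param boundary Domain boundary position (perimeter fraction from the
#'   anterior pole).
#' @param sharpness Logistic boundary steepness.  The default 60 gives a
#'   sharp, near-wild-type boundary so that asymmetry up to ~0.95 is
#'   realizable within the 33% pole arcs.
#' @param fraction Pole-arc fraction defining the estimand (default 0.33).
#' @param ... Passed on to [embryo_spec()] (e.g. `cytoplasm`, `noise_sd`,
#'   `seed`, `af_params`).
#' @return An [embryo_spec()] with membrane channels `apar` and `ppar`.
#' @export
polarized_embryo_spec <- function(target_asi, M = 100, boundary = 0.25,
                                  sharpness = 60, fraction = 0.33, ...) {
  if (target_asi < 0 || target_asi >= 1) stop("`target_asi` must be in [0, 1)")
  f_model <- membrane_model(1, 0, boundary, sharpness)
  fm <- true_arc_means(f_model, fraction)
  D <- fm["anterior"] - fm["posterior"]
  if (target_asi > D) {
    stop(sprintf(
      "target ASI %.3f not realizable: max %.3f at this boundary/sharpness",
      target_asi, D
    ))
  }
  u <- as.numeric((D - target_asi) / (D + target_asi))
  embryo_spec(
    membrane = list(
      apar = membrane_model(M, M * u, boundary, sharpness),
      ppar = membrane_model(M * u, M, boundary, sharpness)
    ),
    ...
  )
}
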