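#' Hill-type dosage-to-phenotype map
#'
#' `p(d) = p_min + (p_wt - p_min) * d^n / (d^n + K^n)`: phenotype `p_min`
#' at zero dosage, approaching the wild-type value `p_wt` at saturation,
#' with inflection near `K` (default 0.5, i.e. near 50% depletion) and
#' steepness `n`.
#'
#' @param d Dosage (dimensionless, control = 1).
#' @param p_min,p_wt Phenotype at zero dosage and at saturation.
#' @param K Half-maximal dosage, in `(0, d_max)`.
#' @param n Hill coefficient (> 0).
#' @return Phenotype values.  Vectorized over `d`.
#' @export
hill_phenotype <- function(d, p_min = 0, p_wt = 1, K = 0.5, n = 6) {
  if (K <= 0) stop("Hill K must be positive")
  if (n <= 0) stop("Hill n must be positive")
  p_min + (p_wt - p_min) * d^n / (d^n + K^n)
}

#' Specification of a dosage-rundown cohort
#'
#' Defines a simulated RNAi rundown: embryo dosages drawn uniformly on a
#' range, Hill-type dosage-to-phenotype maps with additive measurement
#' noise, and a bimodal asymmetry (ASI) regime inside a dosage window in
#' which each embryo either retains near-wild-type asymmetry or falls onto
#' a reduced, linear-in-dosage branch.
#'
#' @param n_embryos Number of embryos (>= 1).
#' @param dosage_range Dosage range `c(0, d_max)` sampled uniformly.
#' @param phenotype_map Named list of Hill parameter lists
#'   (`p_min`, `p_wt`, `K`, `n`), one per phenotype column.  The defaults
#'   give division asynchrony saturating at 120 s (the ~2-min wild-type
#'   AB-P1 delay) and an AB size fraction saturating at 0.57, both with
#'   inflection at 50% dosage.
#' @param noise_sd Named measurement noise SDs, one per phenotype (and
#'   `asi` for the asymmetry index).
#' @param bimodal_window Dosage window with bimodal asymmetry (default
#'   `c(0.25, 0.75)`); above it all embryos retain wild-type asymmetry,
#'   below it none do, and across it the retention probability falls
#'   linearly from 1 (top) to 0 (bottom).
#' @param asi_wt Wild-type ASI level of the retaining population
#'   (default 0.95; "retained" draws stay above the ~0.9 wild-type band).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_embryos = 200,
                        dosage_range = c(0, 1),
                        phenotype_map = list(
                          asynchrony_s = list(p_min = 0, p_wt = 120,
                                              K = 0.5, n = 6),
                          ab_fraction = list(p_min = 0.5, p_wt = 0.57,
                                             K = 0.5, n = 6)
                        ),
                        noise_sd = c(asynchrony_s = 6, ab_fraction = 0.01,
                                     asi = 0.02),
                        bimodal_window = c(0.25, 0.75),
                        asi_wt = 0.95,
                        seed = 1L) {
  if (n_embryos < 1) stop("`n_embryos` must be >= 1")
  d_max <- dosage_range[2]
  for (nm in names(phenotype_map)) {
    pm <- phenotype_map[[nm]]
    if (pm$K <= 0 || pm$K >= d_max) {
      stop(sprintf("phenotype '%s': require K in (0, d_max)", nm))
    }
    if (pm$n <= 0) stop(sprintf("phenotype '%s': require Hill n > 0", nm))
  }
  structure(
    list(n_embryos = as.integer(n_embryos), dosage_range = dosage_range,
         phenotype_map = phenotype_map, noise_sd = noise_sd,
         bimodal_window = bimodal_window, asi_wt = asi_wt,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a dosage-rundown cohort
#'
#' One record per embryo: a dosage drawn uniformly from the spec's range,
#' each phenotype as `Hill(dosage) + noise`, and an asymmetry index from
#' the bimodal regime model: above the bimodal window every embryo retains
#' near-wild-type ASI; inside the window an embryo retains it with a
#' probability falling linearly across the window, otherwise (and below
#' the window) its ASI drops to a reduced branch proportional to dosage.
#'
#' @param spec A [cohort_spec()].
#' @param dosages Optional fixed dosages overriding the uniform draw.
#' @return A list with `cohort` (data frame: `embryo_id`, `dosage_true`,
#'   one column per phenotype, `asi`, `asi_retained`, `seed`) and `truth`
#'   (noiseless phenotype values and the generating parameters).
#' @export
simulate_rundown_cohort <- function(spec, dosages = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_embryos
  with_seed(spec$seed, {
    d <- if (is.null(dosages)) {
      stats::runif(n, spec$dosage_range[1], spec$dosage_range[2])
    } else {
      if (length(dosages) != n) stop("`dosages` must have n_embryos values")
      dosages
    }
    cohort <- data.frame(embryo_id = seq_len(n), dosage_true = d)
    truth <- list(dosage = d, phenotype_true = list(), spec = spec)
    for (nm in names(spec$phenotype_map)) {
      pm <- spec$phenotype_map[[nm]]
      p_true <- hill_phenotype(d, pm$p_min, pm$p_wt, pm$K, pm$n)
      sd_nm <- if (nm %in% names(spec$noise_sd)) spec$noise_sd[[nm]] else 0
      cohort[[nm]] <- p_true + stats::rnorm(n, 0, sd_nm)
      truth$phenotype_true[[nm]] <- p_true
    }
    # bimodal asymmetry regime
    win <- spec$bimodal_window
    p_retain <- pmin(pmax((d - win[1]) / (win[2] - win[1]), 0), 1)
    retained <- stats::runif(n) < p_retain
    asi_true <- ifelse(retained, spec$asi_wt, spec$asi_wt * d / win[2])
    asi_sd <- if ("asi" %in% names(spec$noise_sd)) spec$noise_sd[["asi"]] else 0
    cohort$asi <- asi_true + stats::rnorm(n, 0, asi_sd)
    cohort$asi_retained <- retained
    cohort$seed <- spec$seed
    truth$asi_true <- asi_true
    truth$retained <- retained
    list(cohort = cohort, truth = truth)
  })
}

#' Specification and simulation of a spindle pole track
#'
#' Generates per-frame anterior and posterior pole coordinates: transverse
#' oscillation `y = amplitude * sin(2 pi f t + phase)` plus noise (the
#' posterior pole oscillates at full amplitude, the anterior at
#' `anterior_factor` of it), and `x` drifting at a constant per-pole
#' velocity from the starting positions.  Event annotations (prometaphase,
#' anaphase onset, telophase) are placed at fixed fractions of the track.
#'
#' @param duration_s Track duration (s).
#' @param frame_interval_s Frame interval (s, > 0).
#' @param amplitude_um Posterior-pole transverse oscillation amplitude (um).
#' @param frequency_hz Oscillation frequency (Hz).
#' @param drift_um_per_s Named drift velocities `c(A = ..., P = ...)`
#'   (um/s) along the A-P axis.
#' @param noise_sd Positional noise SD (um).
#' @param embryo_length_um Embryo length (um).
#' @param start_frac Named starting `x` positions as fractions of embryo
#'   length, `c(A = 0.4, P = 0.6)`.
#' @param anterior_factor Anterior amplitude relative to posterior
#'   (default 0.4).
#' @param phase Oscillation phase (rad).
#' @param events Named list of event positions as fractions of the track
#'   (converted to frames).
#' @param seed Integer seed.
#' @return A [spindle_track()]; the ground truth (`amplitude_um`,
#'   expected oscillation SD `amplitude_um / sqrt(2)`, drifts) is attached
#'   as attribute `"truth"`.
#' @export
simulate_spindle_track <- function(duration_s = 300,
                                   frame_interval_s = 15,
                                   amplitude_um = 3,
                                   frequency_hz = 0.05,
                                   drift_um_per_s = c(A = 0, P = 0.01),
                                   noise_sd = 0,
                                   embryo_length_um = 50,
                                   start_frac = c(A = 0.4, P = 0.6),
                                   anterior_factor = 0.4,
                                   phase = 0,
                                   events = list(prometaphase = 0,
                                                 anaphase_onset = 0.6,
                                                 telophase = 1),
                                   seed = 1L) {
  if (frame_interval_s <= 0) stop("`frame_interval_s` must be positive")
  t <- seq(0, duration_s, by = frame_interval_s)
  n <- length(t)
  with_seed(seed, {
    noise <- function() if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    y_P <- amplitude_um * sin(2 * pi * frequency_hz * t + phase) + noise()
    y_A <- anterior_factor * amplitude_um *
      sin(2 * pi * frequency_hz * t + phase + pi) + noise()
    x_A <- start_frac[["A"]] * embryo_length_um +
      drift_um_per_s[["A"]] * t + noise()
    x_P <- start_frac[["P"]] * embryo_length_um +
      drift_um_per_s[["P"]] * t + noise()
    ann <- lapply(events, function(fr) 1L + as.integer(round(fr * (n - 1))))
    tr <- spindle_track(t, x_A, y_A, x_P, y_P, annotations = ann,
                        frame_interval = frame_interval_s,
                        embryo_length = embryo_length_um)
    attr(tr, "truth") <- list(
      amplitude_um = amplitude_um,
      sigma_expected = amplitude_um / sqrt(2),
      anterior_factor = anterior_factor,
      drift_um_per_s = drift_um_per_s,
      final_x_frac = c(
        A = (start_frac[["A"]] * embryo_length_um +
               drift_um_per_s[["A"]] * t[n]) / embryo_length_um,
        P = (start_frac[["P"]] * embryo_length_um +
               drift_um_per_s[["P"]] * t[n]) / embryo_length_um
      )
    )
    tr
  })
}

#' Simulate a two-cell embryo: blastomere masks and division timings
#'
#' Builds midplane masks of the AB and P1 blastomeres by splitting an
#' elliptical whole-embryo mask with a vertical (A-P-perpendicular) plane
#' placed so that the AB (anterior) area fraction matches the target to
#' within one pixel, and returns furrow-ingression event frames separated
#' by the target asynchrony (default the ~2-min wild-type delay).
#'
#' @param ab_fraction Target AB area fraction, in `(0, 1)` (default 0.57).
#' @param asynchrony_s AB-to-P1 furrowing delay (s, default 120).
#' @param frame_interval_s Acquisition interval (s, default 15).
#' @param t_AB_frame Frame of AB furrow ingression (default 40).
#' @param canvas_px Canvas `c(nrow, ncol)` (default `c(240, 400)`).
#' @param semi_axes_px Ellipse semi-axes in pixels; default fills 90% of
#'   the canvas.
#' @return A list with `mask_AB`, `mask_P1`, `mask_whole` (logical
#'   matrices), `event_frames` (`t_AB`, `t_P1`), `event_times_s`, and
#'   `truth` (achieved area fraction and asynchrony).
#' @export
simulate_two_cell <- function(ab_fraction = 0.57, asynchrony_s = 120,
                              frame_interval_s = 15, t_AB_frame = 40,
                              canvas_px = c(240, 400),
                              semi_axes_px = NULL) {
  if (ab_fraction <= 0 || ab_fraction >= 1) {
    stop("`ab_fraction` must be in (0, 1)")
  }
  nr <- canvas_px[1]
  nc <- canvas_px[2]
  if (is.null(semi_axes_px)) {
    semi_axes_px <- c(0.45 * nc, 0.45 * nr)
  }
  a <- semi_axes_px[1]
  b <- semi_axes_px[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- ((col - (nc + 1) / 2) / a)^2 + ((row - (nr + 1) / 2) / b)^2 < 1
  idx <- which(inside)
  # order interior pixels by column (anterior = left), then row: the first
  # round(f * N) pixels form AB, so the achieved area is exact to 1 px
  ord <- idx[order(col[idx], row[idx])]
  n_ab <- round(ab_fraction * length(ord))
  mask_AB <- matrix(FALSE, nr, nc)
  mask_AB[ord[seq_len(n_ab)]] <- TRUE
  mask_P1 <- inside & !mask_AB
  df <- as.integer(round(asynchrony_s / frame_interval_s))
  frames <- c(t_AB = t_AB_frame, t_P1 = t_AB_frame + df)
  list(
    mask_AB = mask_AB, mask_P1 = mask_P1, mask_whole = inside,
    event_frames = frames,
    event_times_s = frames * frame_interval_s,
    truth = list(
      ab_fraction = n_ab / length(ord),
      asynchrony_s = df * frame_interval_s,
      target_ab_fraction = ab_fraction,
      target_asynchrony_s = asynchrony_s
    )
  )
}
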