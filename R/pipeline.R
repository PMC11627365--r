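#' Build a pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Every analysis parameter actually used downstream lives here, and the
#' validated configuration is serialized into the output directory of each
#' run, so a run can be reproduced from its output alone.
#'
#' @param images Directory of embryo TIFFs (written by
#'   [write_embryo_tiff()], with sidecars).
#' @param wt_controls Directory of labeled wild-type control TIFFs (used
#'   for dosage normalization and wild-type peak calibration).
#' @param output Output directory (created if missing).
#' @param af_controls Optional directory of unlabeled control TIFFs; when
#'   given, SAIBR spectral correction is fitted from them and applied to
#'   every signal channel.
#' @param signal_channels Character vector of signal channel roles to
#'   quantify (e.g. `c("apar", "ppar")`).
#' @param af_channel Autofluorescence channel role (default `"af"`).
#' @param segment_channel Role used for segmentation (default the first
#'   signal channel).
#' @param anterior_marker Role of the orientation marker channel
#'   (default the first signal channel) and `anterior_marker_side`, the
#'   side it marks (`"anterior"` or `"posterior"`).
#' @param anterior_marker_side See `anterior_marker`.
#' @param params Named list overriding analysis parameters: `n_points`
#'   (default 1000), `width_px` (50), `smooth_window_px` (20), `fraction`
#'   (0.33), `correction_mode` (`"pixel"`), `seed` (1).
#' @param trend Optional list (`phenotype`, `dose`, `span`, `n_boot`)
#'   requesting a LOWESS trend output.
#' @param varprofile Optional list (`phenotype`, `dose`, `h`, `n_boot`)
#'   requesting a Gaussian-window variance profile output.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(images, wt_controls, output,
                            af_controls = NULL,
                            signal_channels = "signal",
                            af_channel = "af",
                            segment_channel = NULL,
                            anterior_marker = NULL,
                            anterior_marker_side = "anterior",
                            params = list(),
                            trend = NULL,
                            varprofile = NULL) {
  defaults <- list(n_points = 1000, width_px = 50, smooth_window_px = 20,
                   fraction = 0.33, correction_mode = "pixel", seed = 1L)
  params <- utils::modifyList(defaults, params)
  cfg <- structure(
    list(
      version = as.character(utils::packageVersion("parmap")),
      images = images, wt_controls = wt_controls, output = output,
      af_controls = af_controls,
      signal_channels = signal_channels, af_channel = af_channel,
      segment_channel = if (is.null(segment_channel)) signal_channels else segment_channel,
      anterior_marker = if (is.null(anterior_marker)) signal_channels[1] else anterior_marker,
      anterior_marker_side = anterior_marker_side,
      params = params, trend = trend, varprofile = varprofile
    ),
    class = "pipeline_config"
  )
  validate_config(cfg)
  cfg
}

# Schema validation; run before any stage.
validate_config <- function(cfg) {
  if (!dir.exists(cfg$images)) {
    stop(sprintf("config error: image directory '%s' does not exist",
                 cfg$images))
  }
  if (length(list_tiffs(cfg$images)) == 0) {
    stop(sprintf("config error: image directory '%s' contains no TIFFs",
                 cfg$images))
  }
  if (!dir.exists(cfg$wt_controls) ||
      length(list_tiffs(cfg$wt_controls)) == 0) {
    stop("config error: wt_controls must be a directory containing TIFFs")
  }
  if (!is.null(cfg$af_controls) &&
      (!dir.exists(cfg$af_controls) ||
         length(list_tiffs(cfg$af_controls)) == 0)) {
    stop("config error: af_controls must be a directory containing TIFFs")
  }
  if (!cfg$anterior_marker_side %in% c("anterior", "posterior")) {
    stop("config error: anterior_marker_side must be anterior or posterior")
  }
  p <- cfg$params
  if (p$n_points < 16 || p$width_px < 20 || p$fraction <= 0 ||
      p$fraction > 1 || !p$correction_mode %in% c("pixel", "embryo")) {
    stop("config error: invalid analysis parameters")
  }
  invisible(cfg)
}

list_tiffs <- function(dir) {
  sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
}

# Quantify one (already corrected) embryo image: contour, per-channel
# profiles, cortical means, dosages, composite ASI if apar+ppar present.
quantify_embryo <- function(image, cfg, control_means, wt_peaks) {
  p <- cfg$params
  contour <- segment_embryo(
    image, channel = cfg$segment_channel, n_points = p$n_points,
    anterior_channel = cfg$anterior_marker,
    anterior_marker = cfg$anterior_marker_side == "anterior"
  )
  out <- list(contour = contour, profiles = list())
  row <- list()
  for (ch in cfg$signal_channels) {
    st <- straighten_cortex(image, contour, channel = ch,
                            width_px = p$width_px,
                            smooth_window_px = p$smooth_window_px)
    prof <- fit_membrane_profiles(st)
    out$profiles[[ch]] <- prof
    row[[paste0("dosage_", ch)]] <-
      mask_mean(image, contour$mask, channel = ch) / control_means[[ch]]
    row[[paste0("cortical_ant_", ch)]] <-
      cortical_mean(prof, "anterior", fraction = p$fraction)
    row[[paste0("cortical_post_", ch)]] <-
      cortical_mean(prof, "posterior", fraction = p$fraction)
  }
  if (all(c("apar", "ppar") %in% cfg$signal_channels)) {
    row$asi_composite <- asi_composite(
      row$cortical_ant_apar / wt_peaks[["apar"]],
      row$cortical_post_apar / wt_peaks[["apar"]],
      row$cortical_ant_ppar / wt_peaks[["ppar"]],
      row$cortical_post_ppar / wt_peaks[["ppar"]]
    )
    bnd <- domain_boundary(out$profiles[["apar"]], from_pole = "anterior")
    row$boundary_s <- bnd$boundary
  }
  out$row <- row
  out
}

#' Run the end-to-end quantitation pipeline
#'
#' Composes the analysis stages over a directory of embryo images:
#' fluorescence correction (SAIBR from unlabeled controls, when
#' configured), segmentation, cortical straightening, membrane/cytoplasm
#' profile decomposition, polarity metrics and dosage normalization, then
#' optional dose-response outputs (LOWESS trend, Gaussian-window variance
#' profile).  A failing embryo is flagged in the cohort table, not fatal;
#' the run aborts only if more than half the embryos fail.  All numeric
#' outputs are written as full-precision CSV, so identical inputs and
#' configuration give byte-identical outputs; a manifest (config hash,
#' input checksums, per-stage status) is written last.
#'
#' @param config A [pipeline_config()], or the path of a YAML file with
#'   the same fields.
#' @return Invisibly, a list with `cohort` (data frame), `trend`,
#'   `varprofile` (if requested) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, raw)
  }
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  cfg <- config
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  warnings_log <- character(0)

  # --- correction models -------------------------------------------------
  af_models <- NULL
  if (!is.null(cfg$af_controls)) {
    af_files <- list_tiffs(cfg$af_controls)
    af_imgs <- lapply(af_files, read_embryo_tiff)
    af_masks <- lapply(af_imgs, function(im) {
      segment_embryo(im, channel = cfg$af_channel, anterior = "left",
                     refine = "none")$mask
    })
    af_models <- lapply(cfg$signal_channels, function(ch) {
      fit_af_model(af_imgs, af_masks, mode = cfg$params$correction_mode,
                   signal_channel = ch, af_channel = cfg$af_channel)
    })
    names(af_models) <- cfg$signal_channels
    status$af_model <- "ok"
  }
  correct_all <- function(image, mask = NULL) {
    if (is.null(af_models)) return(image)
    for (ch in cfg$signal_channels) {
      image <- correct_image(image, af_models[[ch]],
                             mode = cfg$params$correction_mode,
                             mask = mask, signal_channel = ch,
                             af_channel = cfg$af_channel)
    }
    image
  }

  # --- wild-type control calibration ------------------------------------
  wt_files <- list_tiffs(cfg$wt_controls)
  wt_imgs <- lapply(wt_files, function(f) correct_all(read_embryo_tiff(f)))
  control_means <- stats::setNames(
    rep(NA_real_, length(cfg$signal_channels)), cfg$signal_channels
  )
  wt_peaks <- control_means
  wt_rows <- list()
  for (i in seq_along(wt_imgs)) {
    contour <- segment_embryo(
      wt_imgs[[i]], channel = cfg$segment_channel,
      n_points = cfg$params$n_points,
      anterior_channel = cfg$anterior_marker,
      anterior_marker = cfg$anterior_marker_side == "anterior"
    )
    wt_rows[[i]] <- lapply(cfg$signal_channels, function(ch) {
      st <- straighten_cortex(wt_imgs[[i]], contour, channel = ch,
                              width_px = cfg$params$width_px,
                              smooth_window_px = cfg$params$smooth_window_px)
      prof <- fit_membrane_profiles(st)
      c(mask_mean = mask_mean(wt_imgs[[i]], contour$mask, channel = ch),
        peak = max(prof$positions$A, na.rm = TRUE))
    })
  }
  for (j in seq_along(cfg$signal_channels)) {
    ch <- cfg$signal_channels[j]
    control_means[[ch]] <- mean(vapply(wt_rows, function(r) r[[j]][["mask_mean"]],
                                       numeric(1)))
    wt_peaks[[ch]] <- mean(vapply(wt_rows, function(r) r[[j]][["peak"]],
                                  numeric(1)))
  }
  status$controls <- "ok"

  # --- per-embryo quantitation ------------------------------------------
  files <- list_tiffs(cfg$images)
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    id <- sub("\\.tiff?$", "", basename(files[i]))
    res <- tryCatch({
      img <- correct_all(read_embryo_tiff(files[i]))
      q <- quantify_embryo(img, cfg, control_means, wt_peaks)
      c(list(embryo_id = id), q$row, list(flag = "none"))
    }, error = function(e) {
      warnings_log <<- c(warnings_log,
                         sprintf("%s: %s", id, conditionMessage(e)))
      list(embryo_id = id, flag = "failed")
    })
    rows[[i]] <- res
  }
  n_failed <- sum(vapply(rows, function(r) identical(r$flag, "failed"),
                         logical(1)))
  if (n_failed > length(files) / 2) {
    stop(sprintf("pipeline error: %d of %d embryos failed",
                 n_failed, length(files)))
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  cohort <- do.call(rbind, lapply(rows, function(r) {
    missing <- setdiff(all_cols, names(r))
    r[missing] <- NA
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  write_cohort_csv(cohort, file.path(cfg$output, "cohort.csv"))
  status$quantify <- sprintf("ok (%d embryos, %d failed)",
                             length(files), n_failed)

  # --- dose-response outputs --------------------------------------------
  result <- list(cohort = cohort)
  ok <- cohort$flag == "none"
  if (!is.null(cfg$trend)) {
    tr <- cfg$trend
    fit <- lowess_bootstrap(
      cohort[[tr$dose]][ok], cohort[[tr$phenotype]][ok],
      span = if (is.null(tr$span)) 0.5 else tr$span,
      n_boot = if (is.null(tr$n_boot)) 1000 else tr$n_boot,
      seed = cfg$params$seed
    )
    write_table_precise(fit$grid, file.path(cfg$output, "trend.csv"))
    result$trend <- fit
    status$trend <- "ok"
  }
  if (!is.null(cfg$varprofile)) {
    vp <- cfg$varprofile
    ws <- gaussian_window_stats(
      cohort[[vp$dose]][ok], cohort[[vp$phenotype]][ok],
      h = if (is.null(vp$h)) 0.1 else vp$h,
      n_boot = if (is.null(vp$n_boot)) 1000 else vp$n_boot,
      seed = cfg$params$seed
    )
    write_table_precise(ws$grid, file.path(cfg$output, "varprofile.csv"))
    result$varprofile <- ws
    status$varprofile <- "ok"
  }

  # --- manifest ----------------------------------------------------------
  cfg_path <- file.path(cfg$output, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  inputs <- c(files, wt_files,
              if (!is.null(cfg$af_controls)) list_tiffs(cfg$af_controls))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    inputs = as.list(tools::md5sum(inputs)),
    status = status,
    warnings = warnings_log,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  tmp <- file.path(cfg$output, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(cfg$output, "manifest.json"))
  result$manifest <- manifest
  invisible(result)
}
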