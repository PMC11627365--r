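# Test-side forward model for cross-membrane intensity profiles.  Kept
# independent of render_embryo()/fit_membrane_profiles() so it can serve
# as the oracle for both.
erf_oracle <- function(x) 2 * pnorm(x * sqrt(2)) - 1

profile_model <- function(x, A, C, centre = 0, w_g = 0.5, w_e = 0.5,
                          offset = 0) {
  A * exp(-(x - centre)^2 / (2 * w_g^2)) +
    (C / 2) * (1 + erf_oracle((x - centre) / (w_e * sqrt(2)))) + offset
}

# Build a straightened raster of n_pos profiles with per-position membrane
# amplitude A (scalar or vector), cytoplasm C, and optional noise.
make_profile_raster <- function(A, C = 50, n_pos = 100, width = 50,
                                pixel_size = 0.256, w = 0.5, noise_sd = 0,
                                offset = 0, seed = NULL) {
  x <- (seq_len(width) - (width + 1) / 2) * pixel_size
  A <- rep_len(A, n_pos)
  Y <- t(vapply(seq_len(n_pos), function(i) {
    profile_model(x, A[i], C, w_g = w, w_e = w, offset = offset)
  }, numeric(width)))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    Y <- Y + matrix(rnorm(n_pos * width, 0, noise_sd), n_pos, width)
  }
  straightened_cortex(Y, x, pixel_size = pixel_size)
}

# Rotate all channels of an embryo image by 90 degrees counterclockwise.
rotate_image_90 <- function(image) {
  embryo_image(
    lapply(image$channels, function(m) t(m)[ncol(m):1, , drop = FALSE]),
    image$pixel_size
  )
}

# Render a small cohort of unlabeled (GFP-negative) AF control embryos.
render_af_controls <- function(n, af_means = seq(25, 55, length.out = n),
                               bleed = 0.6, offset = 10, noise_sd = 2,
                               seed0 = 100) {
  lapply(seq_len(n), function(i) {
    render_embryo(embryo_spec(
      membrane = membrane_model(0, 0), cytoplasm = 0,
      af_params = list(af_mean = af_means[i], af_gradient = 10,
                       bleed_factor = bleed),
      offset = offset, noise_sd = noise_sd, seed = seed0 + i
    ))
  })
}

# Write a small on-disk image cohort for pipeline tests: polarized
# two-protein embryos plus wild-type and autofluorescence controls.
make_pipeline_fixture <- function(root, taus = c(0.2, 0.5, 0.8),
                                  noise_sd = 1, seed0 = 10) {
  dirs <- list(images = file.path(root, "images"),
               wt = file.path(root, "wt_controls"),
               af = file.path(root, "af_controls"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  af_par <- list(af_mean = 30, af_gradient = 10, bleed_factor = 0.3)
  truths <- list()
  for (i in seq_along(taus)) {
    sp <- polarized_embryo_spec(taus[i], M = 100, cytoplasm = 30,
                                semi_axes = c(20, 12), af_params = af_par,
                                noise_sd = noise_sd, seed = seed0 + i)
    re <- render_embryo(sp)
    write_embryo_tiff(re$image,
                      file.path(dirs$images, sprintf("embryo_%02d.tif", i)))
    truths[[sprintf("embryo_%02d", i)]] <- re$truth
  }
  for (i in 1:2) {
    sp <- polarized_embryo_spec(0.9, M = 100, cytoplasm = 30,
                                semi_axes = c(20, 12), af_params = af_par,
                                noise_sd = noise_sd, seed = seed0 + 50 + i)
    re <- render_embryo(sp)
    write_embryo_tiff(re$image,
                      file.path(dirs$wt, sprintf("wt_%02d.tif", i)))
  }
  for (i in 1:2) {
    sp <- embryo_spec(membrane = list(apar = membrane_model(0, 0),
                                      ppar = membrane_model(0, 0)),
                      cytoplasm = 0, semi_axes = c(20, 12),
                      af_params = af_par, noise_sd = noise_sd,
                      seed = seed0 + 80 + i)
    re <- render_embryo(sp)
    write_embryo_tiff(re$image,
                      file.path(dirs$af, sprintf("af_%02d.tif", i)))
  }
  c(dirs, list(truths = truths))
}
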