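# Seeded synthetic-microscopy generator. Every scene renders a noiseless
# structural image in arbitrary detector counts, convolves it with an
# isotropic Gaussian PSF of configured FWHM, then applies Poisson shot
# noise plus Gaussian read noise over a constant background. Ground truth
# (object table + label map + the configured effect sizes) is returned
# alongside, so every downstream analysis can be validated exactly.

#' Detection noise model
#'
#' Standard detector model: expected intensity plus a constant background
#' offset is converted to photo-electrons at `photon_scale` electrons per
#' intensity unit, Poisson-sampled, converted back, and Gaussian read noise
#' of SD `read_sigma` is added; the result is clipped at zero.
#'
#' @param photon_scale electrons per intensity unit (> 0). Large values
#'   approach the noise-free limit.
#' @param read_sigma read-noise SD in intensity units (>= 0).
#' @param background_offset constant background in intensity units (>= 0).
#' @return a `NoiseModel` list.
#' @export
noise_model <- function(photon_scale = 1, read_sigma = 2, background_offset = 10) {
  stopifnot(is.finite(photon_scale), photon_scale > 0,
            is.finite(read_sigma), read_sigma >= 0,
            is.finite(background_offset), background_offset >= 0)
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 background_offset = background_offset), class = "NoiseModel")
}

#' Apply detector noise to a noiseless image
#'
#' `output = Poisson(photon_scale * (image + background_offset)) /
#' photon_scale + N(0, read_sigma)`, clipped at 0. Reproducible for a fixed
#' seed. Very large Poisson means (> 2^30 electrons) are drawn from the
#' matching normal approximation to stay within integer range.
#'
#' @param image non-negative numeric array.
#' @param model a [noise_model()].
#' @param seed integer RNG seed.
#' @return noisy array, same shape.
#' @export
apply_noise <- function(image, model, seed) {
  stopifnot(inherits(model, "NoiseModel"))
  if (any(image < 0)) stop("`image` must be non-negative")
  d <- dim(image)
  set.seed(as.integer(seed))
  lam <- model$photon_scale * (image + model$background_offset)
  big <- lam > 2^30
  counts <- numeric(length(lam))
  if (any(!big)) counts[!big] <- stats::rpois(sum(!big), lam[!big])
  if (any(big)) counts[big] <- stats::rnorm(sum(big), lam[big], sqrt(lam[big]))
  out <- counts / model$photon_scale
  if (model$read_sigma > 0) out <- out + stats::rnorm(length(out), 0, model$read_sigma)
  out <- pmax(out, 0)
  dim(out) <- d
  out
}

# ---------------------------------------------------------------------------

#' Scene configuration for the synthetic generator
#'
#' Defaults depend on `scene_kind` and encode the acquisition settings the
#' analyses expect: confocal HeLa fields (300 nm pixels), egg-chamber
#' confocal stills (180 nm pixels, 512 x 512), clathrin-pit STED fields
#' (10 nm pixels, 60 nm PSF), and STED time series (40 nm pixels, ~1 s
#' frames). `tag_ratio` is the ground-truth Halo:SNAP brightness ratio: the
#' dye-channel amplitude is `base_intensity * tag_ratio` for
#' `condition = "halo"` and `base_intensity` for `condition = "snap"`
#' (`"control"` renders no specific dye signal at all).
#'
#' @param scene_kind one of `"hela_field"`, `"egg_chamber"`,
#'   `"clathrin_field"`, `"sted_timeseries"`.
#' @param pixel_size_nm pixel edge, nm.
#' @param image_shape integer `(rows, cols)`, each >= 64.
#' @param n_frames frame count (1 for stills).
#' @param frame_interval_s frame spacing, s.
#' @param tag_ratio ground-truth Halo:SNAP brightness ratio (> 0).
#' @param condition `"halo"`, `"snap"` or `"control"`.
#' @param transfected_fraction fraction of cells carrying the reporter,
#'   in `[0, 1]`.
#' @param labeled_fraction_above_limit fraction of reporter-positive cells
#'   with dye signal above the detection limit, in `[0, 1]`.
#' @param base_intensity mean marker amplitude for the SNAP condition,
#'   intensity units.
#' @param intensity_cv between-cell (or between-image) coefficient of
#'   variation of the marker amplitude.
#' @param bleach_halflife_s photobleaching half-life, s (`Inf` = none).
#' @param psf_fwhm_nm Gaussian PSF FWHM, nm (250 confocal, 60 STED).
#' @param ring_diameter_nm apparent donut diameter of clathrin pits, nm
#'   (see the methods vignette for how the rim radius is compensated for
#'   the PSF).
#' @param noise a [noise_model()].
#' @param seed integer seed; identical configs generate bit-identical
#'   scenes.
#' @return a `SceneConfig` list.
#' @export
scene_config <- function(scene_kind = c("hela_field", "egg_chamber",
                                        "clathrin_field", "sted_timeseries"),
                         pixel_size_nm = NULL, image_shape = NULL,
                         n_frames = NULL, frame_interval_s = NULL,
                         tag_ratio = 1, condition = c("halo", "snap", "control"),
                         transfected_fraction = 0.5,
                         labeled_fraction_above_limit = 1,
                         base_intensity = NULL, intensity_cv = NULL,
                         bleach_halflife_s = Inf, psf_fwhm_nm = NULL,
                         ring_diameter_nm = 100, noise = noise_model(),
                         seed = 1L) {
  scene_kind <- match.arg(scene_kind)
  condition <- match.arg(condition)
  # intensity_cv defaults reflect the unit of replication: broad cell-to-cell
  # expression variability in transfected HeLa fields, but ~10%
  # image-to-image staining/acquisition variability for endogenously tagged
  # tissue and for repeated movies of comparable cells.
  def <- switch(scene_kind,
    hela_field     = list(pixel_size_nm = 300, image_shape = c(384L, 384L),
                          n_frames = 1L, frame_interval_s = 1,
                          base_intensity = 100, psf_fwhm_nm = 250,
                          intensity_cv = 0.2),
    egg_chamber    = list(pixel_size_nm = 180, image_shape = c(512L, 512L),
                          n_frames = 1L, frame_interval_s = 1,
                          base_intensity = 60, psf_fwhm_nm = 250,
                          intensity_cv = 0.1),
    clathrin_field = list(pixel_size_nm = 10, image_shape = c(256L, 256L),
                          n_frames = 1L, frame_interval_s = 1,
                          base_intensity = 150, psf_fwhm_nm = 60,
                          intensity_cv = 0.1),
    sted_timeseries = list(pixel_size_nm = 40, image_shape = c(256L, 256L),
                           n_frames = 40L, frame_interval_s = 1.02,
                           base_intensity = 100, psf_fwhm_nm = 60,
                           intensity_cv = 0.1))
  if (is.null(pixel_size_nm)) pixel_size_nm <- def$pixel_size_nm
  if (is.null(image_shape)) image_shape <- def$image_shape
  if (is.null(n_frames)) n_frames <- def$n_frames
  if (is.null(frame_interval_s)) frame_interval_s <- def$frame_interval_s
  if (is.null(base_intensity)) base_intensity <- def$base_intensity
  if (is.null(psf_fwhm_nm)) psf_fwhm_nm <- def$psf_fwhm_nm
  if (is.null(intensity_cv)) intensity_cv <- def$intensity_cv
  if (scene_kind == "sted_timeseries" && !is.finite(bleach_halflife_s) &&
      missing(bleach_halflife_s)) bleach_halflife_s <- 50
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 64L),
            pixel_size_nm > 0, n_frames >= 1L, frame_interval_s > 0,
            is.finite(tag_ratio), tag_ratio > 0,
            transfected_fraction >= 0, transfected_fraction <= 1,
            labeled_fraction_above_limit >= 0, labeled_fraction_above_limit <= 1,
            base_intensity > 0, intensity_cv >= 0,
            bleach_halflife_s > 0, psf_fwhm_nm > 0, ring_diameter_nm > 0,
            inherits(noise, "NoiseModel"))
  structure(list(scene_kind = scene_kind, pixel_size_nm = pixel_size_nm,
                 image_shape = image_shape, n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s, tag_ratio = tag_ratio,
                 condition = condition,
                 transfected_fraction = transfected_fraction,
                 labeled_fraction_above_limit = labeled_fraction_above_limit,
                 base_intensity = base_intensity, intensity_cv = intensity_cv,
                 bleach_halflife_s = bleach_halflife_s,
                 psf_fwhm_nm = psf_fwhm_nm, ring_diameter_nm = ring_diameter_nm,
                 noise = noise, seed = as.integer(seed)),
            class = "SceneConfig")
}

# marker amplitude multiplier for the configured condition
condition_factor <- function(config) {
  switch(config$condition, halo = config$tag_ratio, snap = 1, control = 0)
}

# squared-distance matrix to a center, in pixels
dist_grid <- function(shape, center) {
  dr <- (seq_len(shape[1]) - center[1])
  dc <- (seq_len(shape[2]) - center[2])
  outer(dr^2, dc^2, "+")
}

draw_disk <- function(shape, center, radius) dist_grid(shape, center) <= radius^2

# ---------------------------------------------------------------------------
# Scene renderers: each returns noiseless channel matrices, a label map
# (object footprints), and the per-object ground-truth table.

# HeLa field: transfected cells are disks visible in the reporter channel;
# co-labeled cells additionally carry 1-3 bright Golgi-like blobs (small
# disks near the cell center, max-composited to keep a flat plateau) in the
# marker channel. Cells sit on a jittered grid so neighbors never touch.
render_hela_field <- function(config) {
  sh <- config$image_shape
  spacing <- 64L; margin <- 32L
  cell_r <- 12
  centers_r <- seq(margin, max(margin, sh[1] - margin), by = spacing)
  centers_c <- seq(margin, max(margin, sh[2] - margin), by = spacing)
  slots <- expand.grid(r = centers_r, c = centers_c)
  fac <- condition_factor(config)
  reporter <- matrix(0, sh[1], sh[2])
  marker <- matrix(0, sh[1], sh[2])
  labels <- matrix(0L, sh[1], sh[2])
  objects <- list()
  id <- 0L
  for (i in seq_len(nrow(slots))) {
    if (stats::runif(1) >= config$transfected_fraction) next
    id <- id + 1L
    ctr <- c(slots$r[i], slots$c[i]) + stats::runif(2, -8, 8)
    rad <- cell_r * stats::runif(1, 0.9, 1.1)
    disk <- draw_disk(sh, ctr, rad)
    rep_amp <- max(stats::rnorm(1, 150, 15), 20)
    reporter[disk] <- rep_amp
    labels[disk] <- id
    colab <- stats::runif(1) < config$labeled_fraction_above_limit
    amp <- 0
    if (colab && fac > 0) {
      # amplitude floored at 40% of the condition mean so that "labeled"
      # cells are above the detection limit by construction
      amp <- max(stats::rnorm(1, config$base_intensity * fac,
                              config$intensity_cv * config$base_intensity * fac),
                 0.4 * config$base_intensity * fac)
      nb <- sample(2:3, 1)
      blob <- matrix(FALSE, sh[1], sh[2])
      for (b in seq_len(nb)) {
        bc <- ctr + stats::runif(2, -0.4 * rad, 0.4 * rad)
        blob <- blob | draw_disk(sh, bc, stats::runif(1, 5, 7))
      }
      blob <- blob & disk
      marker[blob] <- amp
    }
    objects[[id]] <- data.frame(object_id = id, row = ctr[1], col = ctr[2],
                                area_px = sum(disk), mean_intensity = amp,
                                reporter_intensity = rep_amp, colabeled = colab)
  }
  if (id == 0L) stop("generation error: no transfected cell fits the field")
  list(channels = list(reporter = reporter, marker = marker),
       labels = labels, objects = do.call(rbind, objects))
}

# Egg chamber: a ring of follicle epithelium (moderate cytoplasmic signal)
# whose inner rim carries a thin, bright subapical band - the structure the
# DoG + entropy-threshold pipeline is meant to map.
render_egg_chamber <- function(config) {
  sh <- config$image_shape
  fac <- condition_factor(config)
  ctr <- sh / 2 + stats::runif(2, -10, 10)
  r_out <- 0.42 * min(sh) * stats::runif(1, 0.92, 1.05)
  band_w <- 4
  epi_w <- 18
  d2 <- dist_grid(sh, ctr)
  d <- sqrt(d2)
  epi <- d <= r_out & d > r_out - epi_w
  band <- d <= r_out - epi_w & d > r_out - epi_w - band_w
  amp <- max(stats::rnorm(1, config$base_intensity * max(fac, 1e-9),
                          config$intensity_cv * config$base_intensity * max(fac, 1e-9)),
             0.05 * config$base_intensity * max(fac, 1e-9))
  if (fac == 0) amp <- 0
  marker <- matrix(0, sh[1], sh[2])
  marker[epi] <- 0.22 * amp
  marker[band] <- amp
  labels <- matrix(0L, sh[1], sh[2])
  labels[band] <- 1L
  objects <- data.frame(object_id = 1L, row = ctr[1], col = ctr[2],
                        area_px = sum(band), mean_intensity = amp,
                        reporter_intensity = NA_real_, colabeled = fac > 0)
  list(channels = list(marker = marker), labels = labels, objects = objects)
}

# Physical rim radius whose apparent (post-PSF) donut radius equals
# `target_r`. A circle of radius R convolved with an isotropic Gaussian of
# SD s has radial profile proportional to exp(-(r^2+R^2)/(2 s^2)) I0(rR/s^2);
# its peak radius is the fixed point r = R * I1(rR/s^2) / I0(rR/s^2).
# Returns NA when no donut-shaped solution exists (PSF too wide: the
# structure images as a filled spot).
pit_rim_radius <- function(target_r, psf_sigma) {
  peak_of <- function(R) {
    r <- R
    for (i in 1:400) {
      z <- r * R / psf_sigma^2
      r_new <- R * besselI(z, 1, expon.scaled = TRUE) /
        besselI(z, 0, expon.scaled = TRUE)
      if (abs(r_new - r) < 1e-10) { r <- r_new; break }
      r <- r_new
    }
    r
  }
  f <- function(R) peak_of(R) - target_r
  hi <- target_r + 6 * psf_sigma
  if (f(hi) < 0) return(NA_real_)  # even a wide rim peaks inside target
  lo <- target_r
  if (f(lo) > 0) return(target_r)  # negligible blur
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

# Clathrin-pit field: a grid of ring structures near the resolution limit.
# ring_diameter_nm parameterizes the APPARENT donut diameter; the rendered
# rim is placed at the PSF-compensated radius (see pit_rim_radius). Under a
# confocal-width PSF no compensation exists and the rim is drawn at the
# nominal radius - the pits image as blurry spots either way.
render_clathrin_field <- function(config) {
  sh <- config$image_shape
  px <- config$pixel_size_nm
  fac <- condition_factor(config)
  psf_sigma_nm <- fwhm_to_sigma(config$psf_fwhm_nm)
  r_app <- config$ring_diameter_nm / 2
  r_phys <- pit_rim_radius(r_app, psf_sigma_nm)
  resolved_geometry <- !is.na(r_phys)
  if (!resolved_geometry) r_phys <- r_app
  spacing <- floor(min(sh) / 3)
  pos <- seq(spacing %/% 2 + 16, by = spacing, length.out = 3)
  marker <- matrix(0, sh[1], sh[2])
  labels <- matrix(0L, sh[1], sh[2])
  objects <- list()
  id <- 0L
  rim_half_w_nm <- 10
  for (pr in pos) for (pc in pos) {
    id <- id + 1L
    ctr <- c(pr, pc) + stats::runif(2, -4, 4)
    d_nm <- sqrt(dist_grid(sh, ctr)) * px
    ring <- abs(d_nm - r_phys) <= rim_half_w_nm
    amp <- max(stats::rnorm(1, config$base_intensity * max(fac, 1e-9),
                            config$intensity_cv * config$base_intensity * max(fac, 1e-9)), 1)
    if (fac == 0) amp <- 0
    marker[ring] <- amp
    labels[ring] <- id
    objects[[id]] <- data.frame(object_id = id, row = ctr[1], col = ctr[2],
                                area_px = sum(ring), mean_intensity = amp,
                                reporter_intensity = NA_real_, colabeled = fac > 0)
  }
  out <- list(channels = list(marker = marker), labels = labels,
              objects = do.call(rbind, objects))
  out$rim_radius_nm <- r_phys
  out$resolved_geometry <- resolved_geometry
  out
}

# ---------------------------------------------------------------------------

#' Generate a synthetic scene with ground truth
#'
#' Renders the configured scene, convolves each channel with the Gaussian
#' PSF (`psf_fwhm_nm`), applies per-channel detector noise with seeds
#' derived from `config$seed`, and returns the stack together with the
#' exact ground truth of what was rendered. Deterministic: identical
#' configs give bit-identical output.
#'
#' @param config a [scene_config()].
#' @return list with `stack` (an [image_stack()]), `truth` (list:
#'   `objects` data.frame, `labels` integer footprint map,
#'   `noiseless` list of pre-noise channel matrices, configured effect
#'   sizes, and for clathrin scenes the compensated `rim_radius_nm`), and
#'   `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  if (config$scene_kind == "sted_timeseries") return(generate_bleach_series(config))
  set.seed(config$seed)
  scene <- switch(config$scene_kind,
                  hela_field = render_hela_field(config),
                  egg_chamber = render_egg_chamber(config),
                  clathrin_field = render_clathrin_field(config),
                  stop("unknown scene_kind"))
  psf_sigma_px <- fwhm_to_sigma(config$psf_fwhm_nm) / config$pixel_size_nm
  blurred <- lapply(scene$channels, gaussian_blur, sigma_px = psf_sigma_px)
  noisy <- vector("list", length(blurred))
  for (i in seq_along(blurred))
    noisy[[i]] <- apply_noise(blurred[[i]], config$noise,
                              seed = config$seed + 1000L * i)
  arr <- array(0, c(config$image_shape, 1L, length(noisy)))
  for (i in seq_along(noisy)) arr[, , 1L, i] <- noisy[[i]]
  stack <- image_stack(arr, config$pixel_size_nm, config$frame_interval_s,
                       names(scene$channels))
  truth <- list(objects = scene$objects, labels = scene$labels,
                noiseless = blurred, structure = scene$channels,
                tag_ratio = config$tag_ratio, condition = config$condition,
                bleach_halflife_s = config$bleach_halflife_s,
                ring_diameter_nm = config$ring_diameter_nm)
  if (!is.null(scene$rim_radius_nm)) {
    truth$rim_radius_nm <- scene$rim_radius_nm
    truth$resolved_geometry <- scene$resolved_geometry
  }
  list(stack = stack, truth = truth, config = config)
}

#' Generate a photobleaching STED time series
#'
#' The structural image (Golgi-like blobs, as in live STED imaging of a
#' tagged Golgi enzyme) decays mono-exponentially: the expected structure
#' intensity in frame i is `base * 2^(-t_i / halflife)` with
#' `t_i = i * frame_interval_s` (i from 0). Noise is applied independently
#' per frame. `bleach_halflife_s = Inf` encodes "no bleaching".
#'
#' @param config a [scene_config()] with `scene_kind = "sted_timeseries"`
#'   and `n_frames >= 2`.
#' @return as [generate_scene()]; `truth$labels` is the structure footprint
#'   usable as an ROI mask.
#' @export
generate_bleach_series <- function(config) {
  stopifnot(inherits(config, "SceneConfig"),
            config$scene_kind == "sted_timeseries")
  if (config$n_frames < 2L) stop("a time series needs n_frames >= 2")
  set.seed(config$seed)
  sh <- config$image_shape
  fac <- condition_factor(config)
  # structure: a handful of bright blobs in the central third of the field
  structure_img <- matrix(0, sh[1], sh[2])
  labels <- matrix(0L, sh[1], sh[2])
  n_blobs <- 5L
  amp <- max(stats::rnorm(1, config$base_intensity * max(fac, 1e-9),
                          config$intensity_cv * config$base_intensity * max(fac, 1e-9)),
             0.05 * config$base_intensity * max(fac, 1e-9))
  if (fac == 0) amp <- 0
  objects <- list()
  for (b in seq_len(n_blobs)) {
    ctr <- c(stats::runif(1, 0.3, 0.7) * sh[1], stats::runif(1, 0.3, 0.7) * sh[2])
    disk <- draw_disk(sh, ctr, stats::runif(1, 6, 10))
    structure_img[disk] <- amp
    labels[disk] <- b
    objects[[b]] <- data.frame(object_id = b, row = ctr[1], col = ctr[2],
                               area_px = sum(disk), mean_intensity = amp,
                               reporter_intensity = NA_real_, colabeled = fac > 0)
  }
  psf_sigma_px <- fwhm_to_sigma(config$psf_fwhm_nm) / config$pixel_size_nm
  blurred <- gaussian_blur(structure_img, psf_sigma_px)
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval_s
  decay <- if (is.finite(config$bleach_halflife_s))
    2^(-times / config$bleach_halflife_s) else rep(1, config$n_frames)
  arr <- array(0, c(sh, config$n_frames, 1L))
  for (f in seq_len(config$n_frames))
    arr[, , f, 1L] <- apply_noise(blurred * decay[f], config$noise,
                                  seed = config$seed + 7L * f)
  stack <- image_stack(arr, config$pixel_size_nm, config$frame_interval_s, "marker")
  truth <- list(objects = do.call(rbind, objects), labels = labels,
                noiseless = list(marker = blurred),
                structure = list(marker = structure_img),
                decay = decay, times = times,
                tag_ratio = config$tag_ratio, condition = config$condition,
                bleach_halflife_s = config$bleach_halflife_s,
                ring_diameter_nm = config$ring_diameter_nm)
  list(stack = stack, truth = truth, config = config)
}

#' Generate a matched Halo/SNAP scene pair
#'
#' Both scenes share every parameter except the condition: the dye-channel
#' amplitude is `base_intensity * tag_ratio` for the Halo member and
#' `base_intensity` for the SNAP member, so the ratio of noiseless object
#' means equals `tag_ratio` exactly.
#'
#' @param config a [scene_config()] (its `condition` field is overridden).
#' @param seed_offset added to the SNAP member's seed so the two scenes use
#'   independent noise.
#' @return list with elements `halo` and `snap`, each as [generate_scene()].
#' @export
generate_condition_pair <- function(config, seed_offset = 500000L) {
  halo_cfg <- config; halo_cfg$condition <- "halo"
  snap_cfg <- config; snap_cfg$condition <- "snap"
  snap_cfg$seed <- config$seed + as.integer(seed_offset)
  list(halo = generate_scene(halo_cfg), snap = generate_scene(snap_cfg))
}

#' Write a generated scene to disk
#'
#' TIFF via [write_image_stack()] (reporter page before marker page),
#' ground truth as a CSV (one row per object) and the scene configuration
#' as a YAML sidecar.
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory (created if absent).
#' @param name base file name.
#' @return named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  write_image_stack(scene$stack, tif)
  csv <- file.path(dir, paste0(name, "_truth.csv"))
  utils::write.csv(scene$truth$objects, csv, row.names = FALSE)
  cfgp <- file.path(dir, paste0(name, "_config.yaml"))
  cfg <- scene$config
  cfg$noise <- unclass(cfg$noise)
  yaml::write_yaml(lapply(unclass(cfg), function(x) if (is.numeric(x)) as.vector(x) else x), cfgp)
  invisible(c(tiff = tif, truth = csv, config = cfgp))
}
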