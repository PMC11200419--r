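#' Configuration for the synthetic paired-sequence knee phantom
#'
#' The phantom emulates the data structure that pseudo-healthy synthesis
#' exploits: two co-registered sequences of the same knee in which bone
#' marrow lesions are hyperintense in the fluid-sensitive *target* sequence
#' (TSE-like) but near-isointense in the *conditioning* sequence
#' (DESS-like); lesions confined to bone marrow with diffuse, blurred
#' boundaries; and per-volume multiplicative intensity-scale heterogeneity
#' mimicking mixed acquisition bit depths.
#'
#' @param grid_shape integer(3), `(slices, rows, cols)`. Each dimension must
#'   be at least 8.
#' @param bone_fraction_range numeric(2) in (0,1): range of the in-plane
#'   area fraction covered by the two bone components.
#' @param n_lesions_range integer(2): inclusive range of lesion count for
#'   lesioned studies.
#' @param lesion_radius_range numeric(2): in-plane lesion semi-axis range,
#'   voxels.
#' @param boundary_blur_sigma Gaussian sigma (voxels) applied to the lesion
#'   indicator, producing diffuse boundaries. The ground-truth mask is the
#'   blurred field thresholded at half maximum.
#' @param target_lesion_contrast intensity offset added to the target
#'   sequence inside lesions (raw intensity units, before per-volume
#'   scaling).
#' @param conditioning_lesion_contrast offset in the conditioning sequence;
#'   must not exceed `target_lesion_contrast` (the conditioning sequence has
#'   low lesion contrast by design).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param intensity_scale_range per-volume multiplicative scale range.
#' @param n_raters number of simulated annotators per study.
#' @param rater_jitter list with `threshold_sd` (SD of the half-maximum
#'   threshold shift), `morph_max` (maximum in-plane dilation/erosion
#'   radius, voxels), `miss_prob` (probability a rater misses a lesion
#'   entirely). These reproduce the three observed annotator-disagreement
#'   modes: threshold, extent, and presence.
#' @param spacing numeric(3) voxel spacing in mm `(slice, row, col)`.
#' @return a `phantom_config` list.
#' @export
#' @examples
#' cfg <- phantom_config()
#' study <- generate_study(cfg, seed = 1)
#' dim(study$target)
phantom_config <- function(grid_shape = c(16L, 64L, 64L),
                           bone_fraction_range = c(0.12, 0.22),
                           n_lesions_range = c(1L, 3L),
                           lesion_radius_range = c(5, 9),
                           boundary_blur_sigma = 0.8,
                           target_lesion_contrast = 0.5,
                           conditioning_lesion_contrast = 0.05,
                           noise_sd = 0.02,
                           intensity_scale_range = c(0.8, 1.6),
                           n_raters = 2L,
                           rater_jitter = list(threshold_sd = 0.08,
                                               morph_max = 1L,
                                               miss_prob = 0.1),
                           spacing = c(3, 0.7, 0.7)) {
  cfg <- structure(
    list(
      grid_shape = as.integer(grid_shape),
      bone_fraction_range = as.numeric(bone_fraction_range),
      n_lesions_range = as.integer(n_lesions_range),
      lesion_radius_range = as.numeric(lesion_radius_range),
      boundary_blur_sigma = as.numeric(boundary_blur_sigma),
      target_lesion_contrast = as.numeric(target_lesion_contrast),
      conditioning_lesion_contrast = as.numeric(conditioning_lesion_contrast),
      noise_sd = as.numeric(noise_sd),
      intensity_scale_range = as.numeric(intensity_scale_range),
      n_raters = as.integer(n_raters),
      rater_jitter = rater_jitter,
      spacing = as.numeric(spacing)
    ),
    class = "phantom_config"
  )
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  chk_range <- function(r, name, lo = -Inf, hi = Inf) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      abort_bmel(name, " must be a nonempty interval c(low, high)")
    }
    if (r[1] < lo || r[2] > hi) abort_bmel(name, " out of bounds")
  }
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L)) {
    abort_bmel("grid_shape must have 3 dimensions, each at least 8")
  }
  chk_range(cfg$bone_fraction_range, "bone_fraction_range", 0, 1)
  chk_range(cfg$n_lesions_range, "n_lesions_range", 0)
  chk_range(cfg$lesion_radius_range, "lesion_radius_range", 0.5)
  chk_range(cfg$intensity_scale_range, "intensity_scale_range", 0)
  if (cfg$boundary_blur_sigma < 0) abort_bmel("boundary_blur_sigma must be >= 0")
  if (cfg$noise_sd < 0) abort_bmel("noise_sd must be >= 0")
  if (cfg$target_lesion_contrast <= 0) {
    abort_bmel("target_lesion_contrast must be positive")
  }
  if (cfg$conditioning_lesion_contrast < 0 ||
      cfg$conditioning_lesion_contrast > cfg$target_lesion_contrast) {
    abort_bmel(
      "conditioning_lesion_contrast must lie in [0, target_lesion_contrast]"
    )
  }
  if (cfg$n_raters < 1L) abort_bmel("n_raters must be positive")
  invisible(cfg)
}

# Two-bone geometry: per-slice elliptical cross-sections with smooth
# center drift and a through-slice taper. Centers are confined to the
# central ~80% of the field of view so that moderate center crops never
# remove bone.
phantom_geometry <- function(cfg) {
  d <- cfg$grid_shape
  S <- d[1]; R <- d[2]; C <- d[3]
  f <- runif(1, cfg$bone_fraction_range[1], cfg$bone_fraction_range[2])
  centers <- list(
    c(0.35 + runif(1, -0.015, 0.015), 0.45 + runif(1, -0.015, 0.015)),
    c(0.65 + runif(1, -0.015, 0.015), 0.55 + runif(1, -0.015, 0.015))
  )
  mid <- (S + 1) / 2
  bone <- array(FALSE, d)
  rr <- matrix(seq_len(R), R, C)
  cc <- matrix(seq_len(C), R, C, byrow = TRUE)
  for (k in 1:2) {
    rho <- runif(1, 1.1, 1.4)
    area <- f / 2 * R * C
    a <- min(sqrt(area * rho / pi), 0.21 * min(R, C))
    b <- min(area / (pi * a), 0.21 * min(R, C))
    cr0 <- centers[[k]][1] * R
    cc0 <- centers[[k]][2] * C
    phase <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.3, 1.0)
    for (s in seq_len(S)) {
      u <- (s - mid) / (0.65 * S)
      taper <- sqrt(max(0.5, 1 - u^2))
      crs <- cr0 + amp * sin(2 * pi * s / S + phase)
      ccs <- cc0 + amp * cos(2 * pi * s / S + phase)
      inside <- ((rr - crs) / (a * taper))^2 + ((cc - ccs) / (b * taper))^2 <= 1
      bone[s, , ] <- bone[s, , ] | inside
    }
  }
  smooth <- blur3d(array(as.numeric(bone), d), sigma = 0.8, sigma_slice = 0.4)
  bone <- array(smooth > 0.5, d)

  tissue <- array(FALSE, d)
  tis <- ((rr - 0.5 * R) / (0.46 * R))^2 + ((cc - 0.5 * C) / (0.42 * C))^2 <= 1
  for (s in seq_len(S)) tissue[s, , ] <- tis
  tissue <- tissue | bone
  list(bone = bone, tissue = tissue)
}

# Base (lesion-free, noise-free) intensity maps. The target sequence is
# fluid-sensitive and fat-suppressed: normal marrow is dark, soft tissue
# mid-intensity, lesions bright. The conditioning sequence shows marrow
# bright-ish and near-unchanged by lesions.
phantom_base_maps <- function(geom) {
  base_of <- function(air, tissue, marrow) {
    b <- array(air, dim(geom$bone))
    b[geom$tissue] <- tissue
    b[geom$bone] <- marrow
    blur3d(b, sigma = 0.5, sigma_slice = 0.25)
  }
  list(
    target = base_of(0.05, 0.40, 0.15),
    conditioning = base_of(0.05, 0.35, 0.55)
  )
}

# Sample one blurred-ellipsoid lesion field, normalized to unit maximum.
# Returns NULL if no interior bone voxel is available.
phantom_lesion_field <- function(cfg, bone) {
  d <- dim(bone)
  seed_region <- erode3d(bone, 2L)
  if (!any(seed_region)) seed_region <- erode3d(bone, 1L)
  if (!any(seed_region)) seed_region <- bone
  if (!any(seed_region)) return(NULL)
  idx <- which(seed_region)
  center <- arrayInd(idx[sample.int(length(idx), 1L)], d)
  rr <- runif(1, cfg$lesion_radius_range[1], cfg$lesion_radius_range[2])
  rc <- rr * runif(1, 0.8, 1.25)
  rs <- max(1.2, 0.35 * (rr + rc) / 2)
  ind <- array(0, d)
  # bounding box to keep the indicator construction cheap
  lo <- pmax(1, floor(center - c(rs, rr, rc) - 1))
  hi <- pmin(d, ceiling(center + c(rs, rr, rc) + 1))
  for (s in lo[1]:hi[1]) {
    ds2 <- ((s - center[1]) / rs)^2
    if (ds2 > 1) next
    rows <- lo[2]:hi[2]
    cols <- lo[3]:hi[3]
    rg <- matrix(rows, length(rows), length(cols))
    cg <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    inside <- ds2 + ((rg - center[2]) / rr)^2 + ((cg - center[3]) / rc)^2 <= 1
    plane <- ind[s, , ]
    plane[cbind(rg[inside], cg[inside])] <- 1
    ind[s, , ] <- plane
  }
  fld <- blur3d(ind, cfg$boundary_blur_sigma, cfg$boundary_blur_sigma * 0.5)
  m <- max(fld)
  if (m <= 0) return(NULL)
  fld / m
}

#' Generate one synthetic paired-sequence study
#'
#' Deterministic for a fixed `(config, seed)` pair. A lesioned study carries
#' a ground-truth lesion mask (the blurred lesion field thresholded at half
#' maximum, restricted to bone), the continuous per-lesion fields used by
#' [simulate_rater()], simulated rater masks, and `healthy_target`: the
#' target volume with the lesion signal removed but the *same* noise
#' realization, so `healthy_target` equals `target` exactly outside the
#' lesion support.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @param with_lesions if `FALSE`, an entirely healthy study is produced
#'   (`lesion_truth` empty, `target == healthy_target`).
#' @param study_id identifier stored in the study.
#' @return a `paired_study` list with elements `conditioning`, `target`,
#'   `healthy_target`, `bone_mask`, `lesion_truth`, `lesion_field`,
#'   `lesion_fields`, `rater_masks`, `study_id`, `seed`, `spacing`.
#' @export
generate_study <- function(config, seed, with_lesions = TRUE,
                           study_id = sprintf("study_%06d", seed %% 1000000L)) {
  validate_phantom_config(config)
  d <- config$grid_shape
  core <- with_seed(seed, {
    geom <- phantom_geometry(config)
    base <- phantom_base_maps(geom)
    n_lesions <- 0L
    if (with_lesions) {
      n_lesions <- if (config$n_lesions_range[1] == config$n_lesions_range[2]) {
        config$n_lesions_range[1]
      } else {
        sample(config$n_lesions_range[1]:config$n_lesions_range[2], 1L)
      }
    }
    fields <- list()
    if (n_lesions > 0L) {
      for (k in seq_len(n_lesions)) {
        fld <- phantom_lesion_field(config, geom$bone)
        if (!is.null(fld)) fields[[length(fields) + 1L]] <- fld
      }
    }
    field <- array(0, d)
    for (fld in fields) field <- pmax(field, fld)
    truth <- array(FALSE, d)
    for (fld in fields) truth <- truth | (fld >= 0.5 & geom$bone)
    noise_t <- array(rnorm(prod(d), sd = config$noise_sd), d)
    noise_c <- array(rnorm(prod(d), sd = config$noise_sd), d)
    scale_t <- runif(1, config$intensity_scale_range[1],
                     config$intensity_scale_range[2])
    scale_c <- runif(1, config$intensity_scale_range[1],
                     config$intensity_scale_range[2])
    rater_seeds <- sample.int(1000000L, config$n_raters)
    list(
      bone = geom$bone,
      target = (base$target + config$target_lesion_contrast * field + noise_t) *
        scale_t,
      healthy_target = (base$target + noise_t) * scale_t,
      conditioning = (base$conditioning +
                        config$conditioning_lesion_contrast * field + noise_c) *
        scale_c,
      field = field, fields = fields, truth = truth,
      rater_seeds = rater_seeds
    )
  })
  study <- structure(
    list(
      conditioning = core$conditioning,
      target = core$target,
      healthy_target = core$healthy_target,
      bone_mask = core$bone,
      lesion_truth = core$truth,
      lesion_field = core$field,
      lesion_fields = core$fields,
      rater_masks = list(),
      study_id = study_id,
      seed = as.integer(seed),
      spacing = config$spacing
    ),
    class = "paired_study"
  )
  study$rater_masks <- lapply(core$rater_seeds, function(rs) {
    simulate_rater(study, config$rater_jitter, seed = rs)
  })
  names(study$rater_masks) <- sprintf("rater_%d", seq_along(study$rater_masks))
  study
}

#' @export
print.paired_study <- function(x, ...) {
  d <- dim(x$target)
  cat(sprintf(
    "<paired_study '%s'> %dx%dx%d, bone %.1f%%, lesion voxels %d, %d rater(s)\n",
    x$study_id, d[1], d[2], d[3], 100 * mean(x$bone_mask),
    sum(x$lesion_truth), length(x$rater_masks)
  ))
  invisible(x)
}

#' Generate a reproducible set of phantom studies
#'
#' Healthy studies come first (a training set must be lesion-free), then
#' lesioned studies. Every study receives a distinct sub-seed derived
#' deterministically from the master seed.
#'
#' @param config a [phantom_config()].
#' @param n_healthy,n_lesioned study counts.
#' @param seed master seed.
#' @param id_prefix study id prefix.
#' @return list of `paired_study` objects.
#' @export
generate_dataset <- function(config, n_healthy, n_lesioned, seed,
                             id_prefix = "study") {
  n <- n_healthy + n_lesioned
  if (n < 1L) abort_bmel("need at least one study")
  sub_seeds <- with_seed(seed, sample.int(10000000L, n))
  purrr::map(seq_len(n), function(i) {
    generate_study(
      config, seed = sub_seeds[i], with_lesions = i > n_healthy,
      study_id = sprintf("%s_%02d", id_prefix, i)
    )
  })
}

#' Simulate an annotator's lesion mask
#'
#' Perturbs the generator's continuous per-lesion fields the way a
#' semi-automatic annotation workflow does: a rater may miss a lesion
#' entirely (presence disagreement), thresholds the lesion field at a
#' shifted level (threshold disagreement), and dilates or erodes the
#' resulting region in-plane (extent disagreement). The result is always
#' restricted to the bone mask. With all jitter parameters zero the mask
#' equals the ground truth exactly.
#'
#' @param study a `paired_study` produced by [generate_study()] (the
#'   continuous lesion fields are required, so studies reloaded from disk
#'   without them cannot be re-annotated).
#' @param rater_params list with `threshold_sd`, `morph_max`, `miss_prob`,
#'   and optionally `threshold_bias`: a rater's persistent offset of the
#'   segmentation threshold. Giving each rater their own bias while
#'   drawing repeat annotations around it makes repeats by one rater agree
#'   more than annotations across raters, the ordering seen in practice.
#' @param seed integer seed.
#' @return logical 3D array, subset of `study$bone_mask`.
#' @export
simulate_rater <- function(study, rater_params = list(threshold_sd = 0.08,
                                                      morph_max = 1L,
                                                      miss_prob = 0.1),
                           seed = 1L) {
  if (is.null(study$lesion_fields)) {
    abort_bmel("study lacks continuous lesion fields; regenerate with generate_study()")
  }
  p <- rater_params
  thr_sd <- p$threshold_sd %||% 0
  thr_bias <- p$threshold_bias %||% 0
  morph_max <- as.integer(p$morph_max %||% 0L)
  miss_prob <- p$miss_prob %||% 0
  d <- dim(study$bone_mask)
  with_seed(seed, {
    mask <- array(FALSE, d)
    for (fld in study$lesion_fields) {
      if (miss_prob > 0 && runif(1) < miss_prob) next
      tau <- 0.5 + thr_bias + if (thr_sd > 0) rnorm(1, 0, thr_sd) else 0
      tau <- min(max(tau, 0.1), 0.9)
      m <- fld >= tau
      if (morph_max > 0L) {
        r <- sample(seq.int(-morph_max, morph_max), 1L)
        m <- morph2d(m, r)
      }
      mask <- mask | m
    }
    mask & study$bone_mask
  })
}
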