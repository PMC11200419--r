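#' Preprocessing configuration
#'
#' Intensity and spatial standardization applied per volume: per-volume max
#' normalization, clipping at empirical quantiles (inverse-ECDF convention),
#' affine rescaling of the post-clip range onto `out_range`, and an optional
#' center crop of each slice.
#'
#' The inverse-ECDF (type-1) quantile is used so that the whole pipeline is
#' exactly idempotent: re-clipping an already clipped volume finds the same
#' bounds, and re-rescaling an already rescaled volume is the identity.
#'
#' @param q_low,q_high clip quantiles, `0 <= q_low < q_high <= 1`.
#' @param out_range closed output interval, default `c(-1, 1)` to match a
#'   final hyperbolic-tangent activation.
#' @param crop_shape integer(2) `(rows, cols)` per-slice crop target, or
#'   `NULL` for no crop.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(q_low = 0.001, q_high = 0.999,
                              out_range = c(-1, 1), crop_shape = NULL) {
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1)) {
    abort_bmel("need 0 <= q_low < q_high <= 1")
  }
  if (out_range[1] >= out_range[2]) abort_bmel("out_range must have low < high")
  structure(
    list(q_low = q_low, q_high = q_high, out_range = as.numeric(out_range),
         crop_shape = if (!is.null(crop_shape)) as.integer(crop_shape)),
    class = "preprocess_config"
  )
}

# inverse-ECDF empirical quantile (type 1)
quantile1 <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 1, names = FALSE))
}

#' Clip a volume at empirical quantiles
#'
#' Values below the `q_low` quantile or above the `q_high` quantile of the
#' whole volume (all slices jointly) are set to the respective quantile;
#' values in between are unchanged. Quantiles use the inverse-ECDF
#' convention (see [preprocess_config()]).
#'
#' @param volume 3D numeric array.
#' @param config a [preprocess_config()].
#' @return clipped array; the clip bounds are attached as attribute
#'   `clip_bounds`.
#' @export
quantile_clip <- function(volume, config = preprocess_config()) {
  assert_volume(volume)
  if (length(volume) == 0L) abort_bmel("empty volume")
  lo <- quantile1(volume, config$q_low)
  hi <- quantile1(volume, config$q_high)
  out <- pmin(pmax(volume, lo), hi)
  attr(out, "clip_bounds") <- c(lo, hi)
  out
}

#' Affinely rescale a volume onto a target range
#'
#' Maps `[min(volume), max(volume)]` onto `config$out_range`. The map is
#' strictly increasing, so voxel intensity ordering is preserved.
#'
#' @inheritParams quantile_clip
#' @return rescaled array; the fitted map is attached as attribute
#'   `affine` (slope and anchor points).
#' @export
rescale_to_range <- function(volume, config = preprocess_config()) {
  assert_volume(volume)
  lo <- min(volume); hi <- max(volume)
  if (hi <= lo) {
    abort_bmel("cannot rescale a constant volume (degenerate intensity range)",
               class = "bmelseg_degenerate_range")
  }
  r <- config$out_range
  slope <- (r[2] - r[1]) / (hi - lo)
  # anchor at the low endpoint and clamp so both endpoints are exact
  out <- pmin(pmax(r[1] + (volume - lo) * slope, r[1]), r[2])
  attr(out, "affine") <- c(slope = slope, low_in = lo, low_out = r[1],
                           high_out = r[2])
  out
}

#' Center-crop each slice of a volume
#'
#' The slice count is unchanged; rows/cols are cropped to `crop_shape` with
#' the window centered, taking the floor of the offset when the margin is
#' odd.
#'
#' @param volume 3D array `(slices, rows, cols)` (logical or numeric).
#' @param crop_shape integer(2) `(rows, cols)`.
#' @return cropped array.
#' @export
center_crop <- function(volume, crop_shape) {
  if (!is.array(volume) || length(dim(volume)) != 3L) {
    abort_bmel("volume must be a 3D array")
  }
  d <- dim(volume)
  cs <- as.integer(crop_shape)
  if (length(cs) != 2L || any(cs < 1L)) abort_bmel("crop_shape must be 2 positive integers")
  if (cs[1] > d[2] || cs[2] > d[3]) {
    abort_bmel("crop_shape exceeds in-plane volume shape")
  }
  r0 <- floor((d[2] - cs[1]) / 2)
  c0 <- floor((d[3] - cs[2]) / 2)
  volume[, (r0 + 1):(r0 + cs[1]), (c0 + 1):(c0 + cs[2]), drop = FALSE]
}

#' Preprocess a single volume
#'
#' Pipeline: per-volume max normalization, quantile clip, rescale onto
#' `out_range`, center crop. The intensity transform (clip bounds on the
#' max-normalized scale plus the affine) is attached as attribute
#' `intensity_transform` so that a co-registered companion volume can be
#' mapped identically via `apply_transform`.
#'
#' @inheritParams quantile_clip
#' @return preprocessed array.
#' @export
preprocess_volume <- function(volume, config = preprocess_config()) {
  assert_volume(volume)
  mx <- max(abs(volume))
  if (mx <= 0) abort_bmel("cannot preprocess an all-zero volume",
                          class = "bmelseg_degenerate_range")
  v <- volume / mx
  v <- quantile_clip(v, config)
  bounds <- attr(v, "clip_bounds")
  v <- rescale_to_range(v, config)
  aff <- attr(v, "affine")
  if (!is.null(config$crop_shape)) v <- center_crop(v, config$crop_shape)
  attr(v, "intensity_transform") <- list(
    max_norm = mx, clip_bounds = bounds, affine = aff
  )
  attr(v, "clip_bounds") <- NULL
  attr(v, "affine") <- NULL
  v
}

# apply a previously estimated intensity transform to a co-registered volume
apply_transform <- function(volume, transform, config = preprocess_config()) {
  v <- volume / transform$max_norm
  v <- pmin(pmax(v, transform$clip_bounds[1]), transform$clip_bounds[2])
  a <- transform$affine
  v <- pmin(pmax(a[["low_out"]] + (v - a[["low_in"]]) * a[["slope"]],
                 a[["low_out"]]), a[["high_out"]])
  if (!is.null(config$crop_shape)) v <- center_crop(v, config$crop_shape)
  v
}

#' Preprocess a paired study
#'
#' The conditioning and target volumes each receive their own intensity
#' transform. The oracle reference `healthy_target` is mapped with the
#' *target's* transform: the two volumes are co-acquired and identical
#' outside the lesion support, and sharing the transform preserves that
#' exact equality through preprocessing. Masks are cropped only.
#'
#' @param study a `paired_study`.
#' @param config a [preprocess_config()].
#' @return a preprocessed `paired_study` (attribute `preprocessed = TRUE`).
#' @export
preprocess_study <- function(study, config = preprocess_config()) {
  out <- study
  out$target <- preprocess_volume(study$target, config)
  tf <- attr(out$target, "intensity_transform")
  if (!is.null(study$healthy_target)) {
    out$healthy_target <- apply_transform(study$healthy_target, tf, config)
  }
  out$conditioning <- preprocess_volume(study$conditioning, config)
  crop_mask <- function(m) {
    if (is.null(m)) return(NULL)
    if (!is.null(config$crop_shape)) center_crop(m, config$crop_shape) else m
  }
  out$bone_mask <- crop_mask(study$bone_mask)
  out$lesion_truth <- crop_mask(study$lesion_truth)
  out$lesion_field <- crop_mask(study$lesion_field)
  out$lesion_fields <- lapply(study$lesion_fields, crop_mask)
  out$rater_masks <- lapply(study$rater_masks, crop_mask)
  attr(out, "preprocessed") <- TRUE
  attr(out, "preprocess_config") <- config
  out
}

#' Intensity summaries per volume and region
#'
#' Quality-control summary of intensity distributions before/after
#' preprocessing: per volume and per region (whole volume plus any named
#' masks), the voxel count, min/max, quantiles, and histogram bin counts.
#'
#' @param volumes named list of 3D arrays.
#' @param region_masks optional named list (same names as `volumes`) of
#'   named lists of logical masks; the whole volume is always summarized as
#'   region `"all"`.
#' @param n_bins histogram bin count.
#' @return a tibble (class `histogram_report`) with one row per
#'   volume-region and list-columns `breaks`, `counts`.
#' @export
histogram_report <- function(volumes, region_masks = NULL, n_bins = 50L) {
  if (is.null(names(volumes))) {
    names(volumes) <- sprintf("volume_%d", seq_along(volumes))
  }
  rows <- purrr::imap(volumes, function(vol, vid) {
    regions <- list(all = NULL)
    if (!is.null(region_masks) && !is.null(region_masks[[vid]])) {
      regions <- c(regions, region_masks[[vid]])
    }
    purrr::imap(regions, function(msk, rname) {
      vals <- if (is.null(msk)) as.numeric(vol) else as.numeric(vol[msk])
      if (length(vals) == 0L) {
        return(tibble::tibble(
          volume = vid, region = rname, n_voxels = 0L,
          min = NA_real_, q25 = NA_real_, median = NA_real_,
          q75 = NA_real_, max = NA_real_,
          breaks = list(numeric()), counts = list(integer())
        ))
      }
      rng <- range(vals)
      brk <- if (rng[1] == rng[2]) {
        c(rng[1] - 0.5, rng[1] + 0.5)
      } else {
        seq(rng[1], rng[2], length.out = n_bins + 1L)
      }
      h <- hist(vals, breaks = brk, plot = FALSE)
      tibble::tibble(
        volume = vid, region = rname, n_voxels = length(vals),
        min = rng[1],
        q25 = quantile1(vals, 0.25), median = quantile1(vals, 0.5),
        q75 = quantile1(vals, 0.75), max = rng[2],
        breaks = list(h$breaks), counts = list(h$counts)
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("histogram_report", class(out))
  out
}

#' @importFrom graphics hist
NULL
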