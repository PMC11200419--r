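#' Compute an anomaly map from a real and a synthesized target volume
#'
#' The voxel-wise positive part of `real - fake`. Lesions are hyperintense
#' in the target sequence, so only positive differences are lesion
#' evidence; negative differences are synthesis artifacts and are clamped
#' to zero.
#'
#' @param real_target real target-sequence volume (3D array).
#' @param fake_target synthesized pseudo-healthy volume, same shape.
#' @param study_id,backend,task optional provenance tags.
#' @return an `anomaly_map`: list with nonnegative `values` (3D array) and
#'   the tags.
#' @export
compute_anomaly_map <- function(real_target, fake_target, study_id = NULL,
                                backend = NULL, task = NULL) {
  assert_same_shape(real_target, fake_target, "real/fake targets")
  structure(
    list(values = pmax(real_target - fake_target, 0),
         study_id = study_id, backend = backend, task = task,
         bone_masked = FALSE),
    class = "anomaly_map"
  )
}

anomaly_values <- function(map) {
  if (inherits(map, "anomaly_map")) map$values else map
}

#' Restrict an anomaly map to bone
#'
#' Voxels outside the bone mask are set to zero: lesions occur only in
#' bone marrow, so everything outside is a false positive by construction.
#'
#' @param map an `anomaly_map`.
#' @param bone_mask binary 3D array, same shape.
#' @return the masked `anomaly_map`.
#' @export
apply_bone_mask <- function(map, bone_mask) {
  vals <- anomaly_values(map)
  assert_same_shape(vals, bone_mask, "anomaly map/bone mask")
  vals[!bone_mask] <- 0
  if (inherits(map, "anomaly_map")) {
    map$values <- vals
    map$bone_masked <- TRUE
    map
  } else {
    structure(list(values = vals, bone_masked = TRUE), class = "anomaly_map")
  }
}

#' Binarize an anomaly map at a threshold
#'
#' A voxel is positive iff its anomaly value is strictly greater than
#' `tau`.
#'
#' @param map an `anomaly_map` (or bare array).
#' @param tau finite threshold.
#' @return logical 3D array.
#' @export
binarize <- function(map, tau) {
  if (!is.finite(tau) && !identical(tau, Inf) && !identical(tau, -Inf)) {
    abort_bmel("tau must be a number")
  }
  anomaly_values(map) > tau
}

#' Sweep candidate thresholds and score each against the raters
#'
#' For every candidate threshold, all anomaly maps are binarized and the
#' 3D Dice against each rater is computed per volume; scores are averaged
#' across volumes for each rater and then across raters.
#'
#' @param maps list of `anomaly_map` (or 3D arrays), one per volume.
#' @param rater_masks_per_volume list (per volume) of lists (per rater) of
#'   binary 3D arrays.
#' @param grid sorted numeric vector of candidate thresholds.
#' @param epsilon Dice smoothing factor.
#' @return tibble (class `threshold_sweep`) with columns `tau`,
#'   `mean_dice`.
#' @export
sweep_thresholds <- function(maps, rater_masks_per_volume, grid,
                             epsilon = 1e-6) {
  if (length(grid) == 0L) abort_bmel("threshold grid is empty")
  if (is.unsorted(grid)) abort_bmel("threshold grid must be sorted")
  if (length(maps) < 1L) abort_bmel("need at least one anomaly map")
  n_raters <- length(rater_masks_per_volume[[1]])
  if (n_raters < 1L) abort_bmel("need at least one rater")
  mean_dice <- purrr::map_dbl(grid, function(tau) {
    preds <- purrr::map(maps, binarize, tau = tau)
    mean(purrr::map_dbl(seq_len(n_raters), function(r) {
      mean(purrr::map_dbl(seq_along(preds), function(v) {
        dice3d(preds[[v]], rater_masks_per_volume[[v]][[r]], epsilon)
      }))
    }))
  })
  out <- tibble::tibble(tau = as.numeric(grid), mean_dice = mean_dice)
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Pick the optimal threshold from a sweep
#'
#' The threshold attaining the maximal mean Dice; ties are broken towards
#' the smallest threshold (the more sensitive segmentation).
#'
#' @param sweep a `threshold_sweep` tibble from [sweep_thresholds()].
#' @return scalar threshold.
#' @export
select_threshold <- function(sweep) {
  sweep$tau[which.max(sweep$mean_dice)]
}

# default candidate grid: evenly spaced values over the pooled value
# range of the training-fold anomaly maps
threshold_grid <- function(maps, n = 51L) {
  vals <- unlist(lapply(maps, function(m) range(anomaly_values(m))))
  seq(min(vals), max(vals), length.out = n)
}

#' Three-fold cross-validated threshold selection and scoring
#'
#' Test volumes are split into `n_folds` folds (by volume, never by
#' slice). For each fold, the optimal threshold is chosen by
#' [sweep_thresholds()] on the remaining folds, the held-out fold is
#' binarized at that threshold, and its Dice is computed with the
#' volumes-then-raters averaging protocol. The reported score is the
#' arithmetic mean of the fold scores. Fold assignment is deterministic
#' for a fixed seed.
#'
#' @param maps list of bone-masked `anomaly_map`s, one per test volume.
#' @param rater_masks list (per volume) of lists (per rater) of binary 3D
#'   arrays.
#' @param grid candidate thresholds, or `NULL` to use 51 evenly spaced
#'   values over the pooled anomaly-value range of each fold's training
#'   volumes.
#' @param n_folds fold count (default 3).
#' @param seed fold-assignment seed.
#' @param epsilon Dice smoothing factor.
#' @return a `threshold_cv` object: list with `folds` (tibble: `fold`,
#'   `tau`, `dice`, `n_volumes`), `mean_dice`, `assignments`, `sweeps`.
#' @export
threshold_cv <- function(maps, rater_masks, grid = NULL, n_folds = 3L,
                         seed = 1L, epsilon = 1e-6) {
  n <- length(maps)
  if (n < n_folds) {
    abort_bmel("need at least ", n_folds, " volumes for ", n_folds,
               "-fold cross-validation")
  }
  fold_of <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  rows <- vector("list", n_folds)
  sweeps <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train_idx <- which(fold_of != f)
    test_idx <- which(fold_of == f)
    g <- grid %||% threshold_grid(maps[train_idx])
    sw <- sweep_thresholds(maps[train_idx], rater_masks[train_idx], g, epsilon)
    tau <- select_threshold(sw)
    preds <- purrr::map(maps[test_idx], binarize, tau = tau)
    ev <- evaluate_model(preds, rater_masks[test_idx], epsilon)
    rows[[f]] <- tibble::tibble(
      fold = f, tau = tau, dice = attr(ev, "overall"),
      n_volumes = length(test_idx)
    )
    sw$fold <- f
    sweeps[[f]] <- sw
  }
  folds <- dplyr::bind_rows(rows)
  structure(
    list(folds = folds, mean_dice = mean(folds$dice),
         assignments = fold_of, sweeps = dplyr::bind_rows(sweeps),
         seed = as.integer(seed), epsilon = epsilon),
    class = "threshold_cv"
  )
}

#' @export
print.threshold_cv <- function(x, ...) {
  cat(sprintf("<threshold_cv> %d folds, mean Dice %.4f\n",
              nrow(x$folds), x$mean_dice))
  print(x$folds)
  invisible(x)
}

#' @rdname threshold_cv
#' @param x a `threshold_cv` object.
#' @param ... unused.
#' @export
tidy.threshold_cv <- function(x, ...) x$folds

#' @rdname threshold_cv
#' @export
glance.threshold_cv <- function(x, ...) {
  tibble::tibble(
    mean_dice = x$mean_dice, n_folds = nrow(x$folds),
    n_volumes = length(x$assignments), epsilon = x$epsilon
  )
}
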