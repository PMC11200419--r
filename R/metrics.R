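#' Confusion counts between two binary masks
#'
#' Exhaustive voxel tally of true positives, false positives, false
#' negatives, and true negatives.
#'
#' @param pred,truth binary (logical or 0/1) arrays of equal shape.
#' @return a `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth))) {
    abort_bmel("pred and truth must have identical shape")
  }
  p <- as.logical(pred)
  t <- as.logical(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = length(p) - tp - fp - fn),
    class = "confusion_counts"
  )
}

#' Smoothed Dice similarity coefficient
#'
#' `(2*TP + eps) / (2*TP + eps + FP + FN)`. With `eps > 0` the score of two
#' empty masks is exactly 1 (`eps/eps`); with `eps = 0` that case is
#' undefined and raises an error, mirroring the divide-by-zero that makes
#' empty slices drop out of unsmoothed 2D averages.
#'
#' @param counts a `confusion_counts` object (or a list with `tp`, `fp`,
#'   `fn`).
#' @param epsilon nonnegative smoothing factor.
#' @return score in `[0, 1]`.
#' @export
dice <- function(counts, epsilon = 1e-6) {
  if (epsilon < 0) abort_bmel("epsilon must be >= 0")
  num <- 2 * counts$tp + epsilon
  den <- num + (counts$fp + counts$fn)
  if (den == 0) {
    abort_bmel("Dice undefined: TP = FP = FN = 0 with epsilon = 0",
               class = "bmelseg_dice_undefined")
  }
  num / den
}

#' Voxel-wise accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`. Unlike Dice, accuracy is inflated by
#' abundant true negatives, which is why it is unsuitable for small
#' lesions in large volumes.
#'
#' @param counts a `confusion_counts` object.
#' @return score in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  n <- counts$tp + counts$tn + counts$fp + counts$fn
  if (n == 0) abort_bmel("accuracy undefined on zero voxels")
  (counts$tp + counts$tn) / n
}

#' 3D Dice over a whole volume
#'
#' One smoothed Dice over all voxels jointly. Because the counts are
#' pooled, appending slices that are empty in both masks leaves the score
#' unchanged (no empty-slice skew).
#'
#' @param pred_volume,truth_volume binary 3D arrays.
#' @param epsilon smoothing factor.
#' @return score in `[0, 1]`.
#' @export
dice3d <- function(pred_volume, truth_volume, epsilon = 1e-6) {
  dice(confusion(pred_volume, truth_volume), epsilon)
}

#' Mean 2D (slice-wise) Dice
#'
#' Computes the smoothed Dice per slice (first array dimension) and
#' averages. With `epsilon > 0`, slices empty in both masks score exactly
#' 1 and pull the mean towards 1; `scope = "lesion_slices"` instead drops
#' slices whose truth is empty. With `epsilon = 0`, slices with
#' `TP = FP = FN = 0` are undefined; `policy` chooses whether they are
#' skipped or counted as 1.
#'
#' @param pred_volume,truth_volume binary 3D arrays.
#' @param epsilon smoothing factor.
#' @param policy `"skip"` (default; undefined slices are ignored, as a
#'   divide-by-zero would force) or `"include_as_one"`.
#' @param scope `"all_slices"` or `"lesion_slices"` (drop slices with empty
#'   truth).
#' @return mean slice Dice.
#' @export
dice2d <- function(pred_volume, truth_volume, epsilon = 1e-6,
                   policy = c("skip", "include_as_one"),
                   scope = c("all_slices", "lesion_slices")) {
  policy <- match.arg(policy)
  scope <- match.arg(scope)
  assert_same_shape(pred_volume, truth_volume, "pred/truth volumes")
  n_slices <- dim(pred_volume)[1]
  scores <- numeric(0)
  any_lesion <- FALSE
  for (s in seq_len(n_slices)) {
    tr <- truth_volume[s, , ]
    if (scope == "lesion_slices" && !any(tr)) next
    any_lesion <- any_lesion || any(tr)
    cts <- confusion(pred_volume[s, , ], tr)
    if (epsilon == 0 && (2 * cts$tp + cts$fp + cts$fn) == 0) {
      if (policy == "include_as_one") scores <- c(scores, 1)
      next
    }
    scores <- c(scores, dice(cts, epsilon))
  }
  if (scope == "lesion_slices" && !any_lesion) {
    abort_bmel("no lesion-bearing slices in truth volume",
               class = "bmelseg_no_lesion_slices")
  }
  if (length(scores) == 0L) {
    abort_bmel("no slices with a defined Dice score")
  }
  mean(scores)
}

#' Evaluate predicted segmentations against rater annotations
#'
#' The aggregation protocol for model scoring: 3D Dice is computed per
#' volume against each rater, averaged across volumes for each rater, and
#' those per-rater means are then averaged across raters.
#'
#' @param pred_volumes list of binary 3D arrays (one per test volume).
#' @param rater_masks list (per volume) of lists (per rater) of binary 3D
#'   arrays; rater order must be consistent across volumes.
#' @param epsilon smoothing factor.
#' @return a `model_eval` object: tibble with one row per rater
#'   (`rater`, `mean_dice`) and the overall mean as attribute `overall`
#'   (see [glance.model_eval()]).
#' @export
evaluate_model <- function(pred_volumes, rater_masks, epsilon = 1e-6) {
  n_vol <- length(pred_volumes)
  if (n_vol == 0L || length(rater_masks) != n_vol) {
    abort_bmel("need one rater-mask list per predicted volume")
  }
  n_raters <- length(rater_masks[[1]])
  if (n_raters == 0L) abort_bmel("every volume needs at least one rater mask")
  per_rater <- purrr::map_dbl(seq_len(n_raters), function(r) {
    mean(purrr::map_dbl(seq_len(n_vol), function(v) {
      if (length(rater_masks[[v]]) < r) {
        abort_bmel("volume ", v, " is missing a mask for rater ", r)
      }
      dice3d(pred_volumes[[v]], rater_masks[[v]][[r]], epsilon)
    }))
  })
  rater_names <- names(rater_masks[[1]]) %||% sprintf("rater_%d", seq_len(n_raters))
  out <- tibble::tibble(rater = rater_names, mean_dice = per_rater)
  attr(out, "overall") <- mean(per_rater)
  attr(out, "epsilon") <- epsilon
  class(out) <- c("model_eval", class(out))
  out
}

#' @export
print.model_eval <- function(x, ...) {
  NextMethod()
  cat(sprintf("overall (mean of per-rater means): %.4f\n", attr(x, "overall")))
  invisible(x)
}

#' @rdname evaluate_model
#' @param x a `model_eval` object.
#' @param ... unused.
#' @export
glance.model_eval <- function(x, ...) {
  tibble::tibble(
    overall_dice = attr(x, "overall"),
    n_raters = nrow(x),
    epsilon = attr(x, "epsilon")
  )
}

#' Intra-/inter-rater reliability report
#'
#' Every unordered pair of annotation sets is compared volume-by-volume
#' with three Dice summaries (3D; 2D over all slices; 2D over
#' lesion-bearing slices only) and averaged over volumes. Pairs of sets
#' from the same rater form the intra-rater rows; pairs from different
#' raters the inter-rater rows. The returned table averages pairs within
#' each type.
#'
#' @param annotation_sets list of annotation sets; each element is a list
#'   with `rater` (id), `set` (repeat id), and `masks` (list of binary 3D
#'   arrays over the same volumes, in the same order).
#' @param epsilon smoothing factor.
#' @param detail if `TRUE`, return the per-pair table instead of the
#'   type-averaged one.
#' @return tibble (class `reliability_report`) with columns `type`,
#'   `dice_3d`, `dice_2d_all`, `dice_2d_lesion`, `n_pairs`.
#' @export
reliability_report <- function(annotation_sets, epsilon = 1e-6,
                               detail = FALSE) {
  if (length(annotation_sets) < 2L) {
    abort_bmel("need at least two annotation sets")
  }
  n_vol <- length(annotation_sets[[1]]$masks)
  for (a in annotation_sets) {
    if (length(a$masks) != n_vol) {
      abort_bmel("all annotation sets must cover the same volumes")
    }
  }
  combos <- utils::combn(length(annotation_sets), 2L)
  rows <- purrr::map(seq_len(ncol(combos)), function(j) {
    a <- annotation_sets[[combos[1, j]]]
    b <- annotation_sets[[combos[2, j]]]
    d3 <- d2a <- d2l <- numeric(n_vol)
    for (v in seq_len(n_vol)) {
      d3[v] <- dice3d(a$masks[[v]], b$masks[[v]], epsilon)
      d2a[v] <- dice2d(a$masks[[v]], b$masks[[v]], epsilon, scope = "all_slices")
      d2l[v] <- tryCatch(
        dice2d(a$masks[[v]], b$masks[[v]], epsilon, scope = "lesion_slices"),
        bmelseg_no_lesion_slices = function(e) NA_real_
      )
    }
    tibble::tibble(
      rater_a = as.character(a$rater), set_a = as.character(a$set %||% 1),
      rater_b = as.character(b$rater), set_b = as.character(b$set %||% 1),
      type = if (identical(as.character(a$rater), as.character(b$rater)))
        "intra_rater" else "inter_rater",
      dice_3d = mean(d3), dice_2d_all = mean(d2a),
      dice_2d_lesion = mean(d2l, na.rm = TRUE)
    )
  })
  pairs_tbl <- dplyr::bind_rows(rows)
  if (detail) {
    class(pairs_tbl) <- c("reliability_report", class(pairs_tbl))
    return(pairs_tbl)
  }
  out <- pairs_tbl |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      dice_3d = mean(.data$dice_3d),
      dice_2d_all = mean(.data$dice_2d_all),
      dice_2d_lesion = mean(.data$dice_2d_lesion),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$type == "intra_rater"))
  class(out) <- c("reliability_report", class(out))
  out
}
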