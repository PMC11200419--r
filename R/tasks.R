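#' Conditioning tasks
#'
#' The three ways a (conditioning, target) slice pair is assembled:
#' * `sequence_translation`: the conditioning image is the full
#'   conditioning-sequence slice; the target is the full target-sequence
#'   slice.
#' * `bone_inpainting`: the conditioning image is the target-sequence slice
#'   with its bone voxels removed (set to `fill_value`); the model learns to
#'   inpaint healthy bone from the surroundings.
#' * `bone_translation`: sequence translation restricted to bone; non-bone
#'   voxels of both images are set to `fill_value`.
#'
#' @return character vector of valid task names.
#' @export
task_kinds <- function() {
  c("sequence_translation", "bone_inpainting", "bone_translation")
}

#' Build one (conditioning, target) pair from a study slice
#'
#' @param study a (preprocessed) `paired_study`.
#' @param slice_index slice number along the first array dimension.
#' @param task one of [task_kinds()].
#' @param fill_value intensity used for masked-out voxels; defaults to -1,
#'   the low end of the preprocessing output range, so masked regions read
#'   as empty background.
#' @return a `conditioning_pair`: list with 2D matrices `conditioning`,
#'   `target`, `bone_mask_slice`, plus `study_id`, `slice_index`, `task`.
#' @export
build_pair <- function(study, slice_index, task, fill_value = -1) {
  task <- match.arg(task, task_kinds())
  n_slices <- dim(study$target)[1]
  if (slice_index < 1L || slice_index > n_slices) {
    abort_bmel("slice_index ", slice_index, " out of range 1..", n_slices)
  }
  tgt <- study$target[slice_index, , ]
  cond_seq <- study$conditioning[slice_index, , ]
  bone <- study$bone_mask[slice_index, , ]
  if (task == "sequence_translation") {
    c_img <- cond_seq
    x_img <- tgt
  } else if (task == "bone_inpainting") {
    c_img <- tgt
    c_img[bone] <- fill_value
    x_img <- tgt
  } else {
    c_img <- cond_seq
    c_img[!bone] <- fill_value
    x_img <- tgt
    x_img[!bone] <- fill_value
  }
  structure(
    list(conditioning = c_img, target = x_img, bone_mask_slice = bone,
         study_id = study$study_id, slice_index = as.integer(slice_index),
         task = task, fill_value = fill_value),
    class = "conditioning_pair"
  )
}

#' Build the healthy training pair set
#'
#' One pair per slice per study, ordered by `(study_id, slice_index)`.
#' Every study must be lesion-free: the framework's premise is that the
#' generator is trained only on healthy anatomy.
#'
#' @param studies list of healthy `paired_study` objects.
#' @param task one of [task_kinds()].
#' @param fill_value see [build_pair()].
#' @return list of `conditioning_pair` objects.
#' @export
build_training_set <- function(studies, task, fill_value = -1) {
  task <- match.arg(task, task_kinds())
  for (st in studies) {
    if (sum(st$lesion_truth) > 0L) {
      abort_bmel(
        "training study '", st$study_id, "' contains ", sum(st$lesion_truth),
        " lesion voxels; the training set must be healthy",
        class = "bmelseg_lesioned_training"
      )
    }
  }
  ord <- order(purrr::map_chr(studies, "study_id"))
  pairs <- purrr::map(studies[ord], function(st) {
    purrr::map(seq_len(dim(st$target)[1]), function(s) {
      build_pair(st, s, task, fill_value)
    })
  })
  purrr::flatten(pairs)
}
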