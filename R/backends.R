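#' Train a generative backend on healthy conditioning pairs
#'
#' All backends share one contract: train on healthy (conditioning,
#' target) pairs, then synthesize a pseudo-healthy target image from a
#' conditioning image. Downstream anomaly-map, thresholding, and metric
#' code treats the backend as a black box.
#'
#' @param backend a backend object ([cgan_backend()],
#'   [diffusion_backend()], or [oracle_backend()]).
#' @param pairs list of `conditioning_pair` from [build_training_set()].
#' @param seed integer training seed.
#' @param ... backend-specific options.
#' @return the trained backend.
#' @export
backend_train <- function(backend, pairs, seed = 1L, ...) {
  UseMethod("backend_train")
}

#' Synthesize a pseudo-healthy target slice
#'
#' @param backend a trained backend.
#' @param pair a `conditioning_pair` (the oracle backend uses its identity
#'   fields; the generative backends use only `pair$conditioning`).
#' @param ... backend-specific options (e.g. `sampling_seed`).
#' @return matrix shaped like `pair$conditioning`, values in the
#'   configured output range.
#' @export
backend_synthesize <- function(backend, pair, ...) {
  UseMethod("backend_synthesize")
}

#' Perfect-generator oracle backend
#'
#' Returns the phantom's noise-matched healthy target slice for any
#' requested `(study_id, slice_index)`. This is the idealized generator:
#' downstream of it, the anomaly map contains exactly the lesion signal,
#' which makes it the reference point for testing the segmentation
#' framework independently of generative-model quality.
#'
#' @param studies list of (preprocessed) `paired_study` objects with
#'   `healthy_target` volumes.
#' @return object of class `c("oracle_backend", "bmel_backend")`.
#' @export
oracle_backend <- function(studies) {
  lookup <- new.env(parent = emptyenv())
  for (st in studies) {
    if (is.null(st$healthy_target)) {
      abort_bmel("study '", st$study_id, "' has no healthy_target volume")
    }
    for (s in seq_len(dim(st$healthy_target)[1])) {
      assign(paste0(st$study_id, "#", s), st$healthy_target[s, , ],
             envir = lookup)
    }
  }
  structure(
    list(lookup = lookup, trained = TRUE),
    class = c("oracle_backend", "bmel_backend")
  )
}

#' @rdname backend_train
#' @export
backend_train.oracle_backend <- function(backend, pairs, seed = 1L, ...) {
  backend  # nothing to learn
}

#' @rdname backend_synthesize
#' @export
backend_synthesize.oracle_backend <- function(backend, pair, ...) {
  key <- paste0(pair$study_id, "#", pair$slice_index)
  if (!exists(key, envir = backend$lookup, inherits = FALSE)) {
    abort_bmel("oracle backend has no healthy reference for ", key,
               class = "bmelseg_oracle_miss")
  }
  get(key, envir = backend$lookup, inherits = FALSE)
}

#' Synthesize a pseudo-healthy target volume for a whole study
#'
#' Builds the task's conditioning image for every slice, synthesizes each
#' slice with the backend, and stacks the results.
#'
#' @param backend a trained backend.
#' @param study a (preprocessed) `paired_study`.
#' @param task one of [task_kinds()].
#' @param fill_value masked-voxel fill, see [build_pair()].
#' @param ... passed to [backend_synthesize()].
#' @return 3D array shaped like `study$target`.
#' @export
synthesize_healthy <- function(backend, study, task, fill_value = -1, ...) {
  d <- dim(study$target)
  out <- array(0, d)
  for (s in seq_len(d[1])) {
    pr <- build_pair(study, s, task, fill_value)
    out[s, , ] <- backend_synthesize(backend, pr, ...)
  }
  out
}
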