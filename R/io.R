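#' Write a paired study to a directory of NIfTI volumes
#'
#' Writes `conditioning.nii.gz`, `target.nii.gz`, `healthy_target.nii.gz`,
#' `bone.nii.gz`, `lesion.nii.gz`, and `rater_<k>.nii.gz`, plus a
#' `study.json` sidecar carrying the study id, seed, and spacing. The
#' continuous lesion fields are generator internals and are not persisted;
#' a reloaded study therefore supports everything except re-running
#' [simulate_rater()].
#'
#' @param study a `paired_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(arr, name) {
    img <- array(as.numeric(arr), dim(arr))
    RNifti::writeNifti(
      RNifti::asNifti(img, pixdim = study$spacing %||% c(1, 1, 1)),
      file.path(dir, paste0(name, ".nii.gz"))
    )
  }
  wr(study$conditioning, "conditioning")
  wr(study$target, "target")
  if (!is.null(study$healthy_target)) wr(study$healthy_target, "healthy_target")
  wr(study$bone_mask, "bone")
  wr(study$lesion_truth, "lesion")
  for (k in seq_along(study$rater_masks)) {
    wr(study$rater_masks[[k]], sprintf("rater_%d", k))
  }
  jsonlite::write_json(
    list(study_id = study$study_id, seed = study$seed,
         spacing = study$spacing, shape = dim(study$target),
         n_raters = length(study$rater_masks)),
    file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

read_nifti_array <- function(path, logical = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (logical) array(arr > 0.5, dim(arr)) else arr
}

#' Read a paired study written by [write_study()]
#'
#' @param dir study directory.
#' @return a `paired_study` (without the generator's continuous lesion
#'   fields).
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  rd <- function(name, logical = FALSE) {
    p <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(p)) return(NULL)
    read_nifti_array(p, logical)
  }
  raters <- list()
  k <- 1L
  repeat {
    m <- rd(sprintf("rater_%d", k), logical = TRUE)
    if (is.null(m)) break
    raters[[sprintf("rater_%d", k)]] <- m
    k <- k + 1L
  }
  structure(
    list(conditioning = rd("conditioning"), target = rd("target"),
         healthy_target = rd("healthy_target"),
         bone_mask = rd("bone", logical = TRUE),
         lesion_truth = rd("lesion", logical = TRUE),
         lesion_field = NULL, lesion_fields = NULL,
         rater_masks = raters, study_id = meta$study_id,
         seed = meta$seed, spacing = meta$spacing),
    class = "paired_study"
  )
}

#' Write a dataset of studies with a manifest
#'
#' @param studies list of `paired_study`.
#' @param dir output directory.
#' @param extra named list merged into the manifest (e.g. config hash,
#'   master seed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(studies, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in studies) write_study(st, file.path(dir, st$study_id))
  manifest <- c(
    list(studies = purrr::map_chr(studies, "study_id"),
         n = length(studies)),
    extra
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list of `paired_study`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  purrr::map(manifest$studies, ~ read_study(file.path(dir, .x)))
}

#' Reliability report from directories of rater masks
#'
#' Each annotation set is a directory of NIfTI masks with one file per
#' volume; file names (minus extension) are the volume ids and must match
#' across sets.
#'
#' @param sets a data frame (or tibble) with columns `rater`, `set`,
#'   `dir`.
#' @param epsilon Dice smoothing factor.
#' @return a `reliability_report` tibble (see [reliability_report()]).
#' @export
reliability_from_dirs <- function(sets, epsilon = 1e-6) {
  sets <- tibble::as_tibble(sets)
  load_set <- function(dir) {
    files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
    stats::setNames(lapply(files, read_nifti_array, logical = TRUE), ids)
  }
  loaded <- purrr::pmap(sets, function(rater, set, dir) {
    list(rater = rater, set = set, masks = load_set(dir))
  })
  ids <- names(loaded[[1]]$masks)
  for (a in loaded) {
    missing <- setdiff(ids, names(a$masks))
    extra <- setdiff(names(a$masks), ids)
    if (length(missing) || length(extra)) {
      abort_bmel(
        "volume lists differ between annotation sets; ",
        if (length(missing)) paste0("missing: ", paste(missing, collapse = ", ")),
        if (length(extra)) paste0(" extra: ", paste(extra, collapse = ", "))
      )
    }
    # enforce shared ordering
  }
  loaded <- purrr::map(loaded, function(a) {
    a$masks <- a$masks[ids]
    a
  })
  reliability_report(loaded, epsilon = epsilon)
}
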