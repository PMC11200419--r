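#' Run the full unsupervised segmentation pipeline on phantom data
#'
#' End to end: generate a phantom dataset (healthy training studies plus
#' lesioned test studies), preprocess, build training pairs for each task,
#' train the backend, synthesize pseudo-healthy volumes, form bone-masked
#' anomaly maps, select binarization thresholds by three-fold
#' cross-validation, and report the mean test Dice per backend-task
#' combination.
#'
#' @param backends character vector naming backends (`"oracle"`,
#'   `"cgan"`, `"diffusion"`) or a named list of backend objects.
#' @param tasks subset of [task_kinds()].
#' @param phantom a [phantom_config()].
#' @param n_train healthy training study count.
#' @param n_test lesioned test study count (>= 3 for the default
#'   three-fold CV).
#' @param preprocess a [preprocess_config()].
#' @param annotations `"raters"` to score against the simulated rater
#'   masks, `"truth"` to score against the generator ground truth.
#' @param cgan,diffusion backend configs used when backends are named by
#'   string.
#' @param grid optional fixed threshold grid for the CV.
#' @param epsilon Dice smoothing factor.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `bmel_run`: list with `report` (tibble: backend, task,
#'   mean_dice, fold details), `cv` (named list of `threshold_cv`),
#'   `seed`, `config_hash`.
#' @export
run_pipeline <- function(backends = "oracle",
                         tasks = task_kinds(),
                         phantom = phantom_config(),
                         n_train = 4L, n_test = 6L,
                         preprocess = preprocess_config(),
                         annotations = c("raters", "truth"),
                         cgan = cgan_config(),
                         diffusion = diffusion_config(),
                         grid = NULL, epsilon = 1e-6, seed = 1L) {
  annotations <- match.arg(annotations)
  tasks <- match.arg(tasks, task_kinds(), several.ok = TRUE)
  studies <- generate_dataset(phantom, n_train, n_test, seed)
  studies <- purrr::map(studies, preprocess_study, config = preprocess)
  train_studies <- studies[seq_len(n_train)]
  test_studies <- studies[n_train + seq_len(n_test)]

  rater_masks <- purrr::map(test_studies, function(st) {
    if (annotations == "truth") list(truth = st$lesion_truth) else st$rater_masks
  })

  make_backend <- function(name) {
    switch(name,
      oracle = oracle_backend(test_studies),
      cgan = cgan_backend(cgan),
      diffusion = diffusion_backend(diffusion),
      abort_bmel("unknown backend '", name, "'")
    )
  }
  if (is.character(backends)) {
    backends <- stats::setNames(lapply(backends, make_backend), backends)
  }

  cvs <- list()
  rows <- list()
  for (bk_name in names(backends)) {
    for (task in tasks) {
      pairs <- build_training_set(train_studies, task)
      trained <- backend_train(backends[[bk_name]], pairs,
                               seed = seed + 17L * match(task, task_kinds()))
      maps <- purrr::map(test_studies, function(st) {
        fake <- synthesize_healthy(trained, st, task)
        apply_bone_mask(
          compute_anomaly_map(st$target, fake, study_id = st$study_id,
                              backend = bk_name, task = task),
          st$bone_mask
        )
      })
      cv <- threshold_cv(maps, rater_masks, grid = grid, seed = seed,
                         epsilon = epsilon)
      key <- paste(bk_name, task, sep = ".")
      cvs[[key]] <- cv
      rows[[key]] <- tibble::tibble(
        backend = bk_name, task = task, mean_dice = cv$mean_dice,
        folds = list(cv$folds)
      )
    }
  }
  report <- dplyr::bind_rows(rows)
  structure(
    list(report = report, cv = cvs, seed = as.integer(seed),
         epsilon = epsilon,
         config_hash = rlang::hash(list(phantom, preprocess, tasks,
                                        names(backends), n_train, n_test))),
    class = "bmel_run"
  )
}

#' @export
print.bmel_run <- function(x, ...) {
  cat(sprintf("<bmel_run> seed %d, config %s\n", x$seed, x$config_hash))
  print(dplyr::select(x$report, -"folds"))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `bmel_run`.
#' @param ... unused.
#' @export
tidy.bmel_run <- function(x, ...) {
  tidyr::unnest(x$report, "folds", names_sep = "_")
}

#' @rdname run_pipeline
#' @export
glance.bmel_run <- function(x, ...) {
  tibble::tibble(
    n_combinations = nrow(x$report),
    best_dice = max(x$report$mean_dice),
    best_backend = x$report$backend[which.max(x$report$mean_dice)],
    best_task = x$report$task[which.max(x$report$mean_dice)],
    seed = x$seed
  )
}
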