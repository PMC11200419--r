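# Shared fixtures: built once per test run, in code.

# small, quiet phantom configuration used by most framework tests
small_phantom <- function(noise_sd = 0.01, ...) {
  phantom_config(grid_shape = c(8L, 32L, 32L), lesion_radius_range = c(4, 6),
                 noise_sd = noise_sd, ...)
}

# default-size phantom with low noise for the oracle end-to-end checks
oracle_phantom <- function() {
  phantom_config(noise_sd = 0.005)
}

# cache expensive fixtures across tests within one run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# a preprocessed 6-volume lesioned test set plus its bone-masked oracle
# anomaly maps (the oracle backend makes the maps exactly the lesion signal)
oracle_maps_fixture <- function() {
  cached("oracle_maps", {
    studies <- generate_dataset(oracle_phantom(), n_healthy = 0,
                                n_lesioned = 6, seed = 404)
    studies <- lapply(studies, preprocess_study)
    backend <- oracle_backend(studies)
    maps <- lapply(studies, function(st) {
      fake <- synthesize_healthy(backend, st, "sequence_translation")
      apply_bone_mask(compute_anomaly_map(st$target, fake), st$bone_mask)
    })
    list(studies = studies, maps = maps,
         raters = lapply(studies, function(st) list(truth = st$lesion_truth)))
  })
}

# toy binary volumes with prescribed 3D Dice values (epsilon = 0)
mask_from_idx <- function(idx, dims = c(1L, 4L, 4L)) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  m
}

# independent 3D Dice oracle: plain sums, no package code
dice_oracle <- function(pred, truth, eps = 0) {
  tp <- sum(pred & truth)
  (2 * tp + eps) / (2 * tp + eps + sum(pred & !truth) + sum(!pred & truth))
}
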