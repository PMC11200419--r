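test_that("quantile clipping matches a sort-based oracle and its edge cases", {
  # constant volume: quantiles coincide, nothing changes
  const <- array(3, c(2, 4, 4))
  expect_equal(as.numeric(quantile_clip(const)), rep(3, 32))
  # full-range quantiles: identity
  ramp <- array(seq(0, 1, length.out = 1000), c(10, 10, 10))
  wide <- quantile_clip(ramp, preprocess_config(q_low = 0, q_high = 1))
  expect_equal(as.numeric(wide), as.numeric(ramp))
  # inverse-ECDF oracle: explicit sort + index
  clipped <- quantile_clip(ramp, preprocess_config(q_low = 0.001, q_high = 0.999))
  s <- sort(as.numeric(ramp))
  expect_equal(min(clipped), s[ceiling(1000 * 0.001)])
  expect_equal(max(clipped), s[ceiling(1000 * 0.999)])
  # interior values untouched
  inner <- ramp > s[5] & ramp < s[995]
  expect_equal(clipped[inner], ramp[inner])
})

test_that("range rescaling maps endpoints exactly and rejects constants", {
  v <- array(c(0, 2.5, 5, 7.5, 10, rep(4, 11)), c(1, 4, 4))
  out <- rescale_to_range(v, preprocess_config())
  expect_equal(min(out), -1)
  expect_equal(max(out), 1)
  expect_equal(out[v == 5], 0)  # midpoint maps to midpoint
  expect_error(rescale_to_range(array(1, c(1, 4, 4))),
               class = "bmelseg_degenerate_range")
})

test_that("center crop uses the centered floor-offset window", {
  slice <- array(seq_len(320 * 320), c(1, 320, 320))
  out <- center_crop(slice, c(256, 256))
  expect_equal(dim(out), c(1L, 256L, 256L))
  # 32-voxel margins on each side
  expect_identical(out[1, , ], slice[1, 33:288, 33:288])
  # identity crop
  expect_identical(center_crop(slice, c(320, 320)), slice)
  # odd-remainder convention on a small case
  tiny <- array(seq_len(25), c(1, 5, 5))
  expect_identical(center_crop(tiny, c(3, 3)), tiny[, 2:4, 2:4, drop = FALSE])
  expect_error(center_crop(tiny, c(6, 6)), "exceeds")
})

test_that("the clip-rescale-crop pipeline is idempotent and order-preserving", {
  st <- generate_study(small_phantom(noise_sd = 0.03), seed = 13)
  pc <- preprocess_config()
  v1 <- preprocess_volume(st$target, pc)
  v2 <- preprocess_volume(array(as.numeric(v1), dim(v1)), pc)
  expect_lt(max(abs(v1 - v2)), 1e-6)
  # monotonicity: intensity ordering preserved by the affine rescale
  raw <- as.numeric(st$target)
  cooked <- as.numeric(rescale_to_range(st$target))
  pick <- sample.int(length(raw), 500)
  expect_identical(order(raw[pick]), order(cooked[pick]))
})

test_that("a moderate center crop never removes bone on phantom defaults", {
  for (seed in c(2, 8)) {
    st <- generate_study(phantom_config(), seed = seed)
    cropped <- center_crop(st$bone_mask, c(52, 52))
    expect_equal(sum(cropped), sum(st$bone_mask))
  }
})

test_that("preprocessing preserves the pseudo-healthy equality and unifies scales", {
  # two volumes of the same anatomy at very different raw scales end up in
  # identical ranges after preprocessing
  cfg_lo <- small_phantom(intensity_scale_range = c(0.5, 0.5))
  cfg_hi <- small_phantom(intensity_scale_range = c(4, 4))
  lo <- preprocess_study(generate_study(cfg_lo, seed = 31))
  hi <- preprocess_study(generate_study(cfg_hi, seed = 31))
  rep_tbl <- histogram_report(list(lo = lo$target, hi = hi$target))
  expect_equal(rep_tbl$min, c(-1, -1))
  expect_equal(rep_tbl$max, c(1, 1))
  expect_equal(lo$target, hi$target, tolerance = 1e-12, ignore_attr = TRUE)
  # healthy reference shares the target transform: exact equality outside
  outside <- lo$lesion_field == 0
  expect_identical(lo$target[outside], lo$healthy_target[outside])
})

test_that("histogram report covers regions and respects masks", {
  st <- preprocess_study(generate_study(small_phantom(), seed = 41))
  all_mask <- array(TRUE, dim(st$target))
  rep_tbl <- histogram_report(
    list(a = st$target),
    region_masks = list(a = list(everything = all_mask, bone = st$bone_mask))
  )
  expect_equal(rep_tbl$region, c("all", "everything", "bone"))
  expect_gte(min(rep_tbl$min), -1)
  expect_lte(max(rep_tbl$max), 1)
  # an all-ones mask reproduces the whole-volume row
  expect_equal(rep_tbl$counts[[1]], rep_tbl$counts[[2]])
  expect_equal(rep_tbl$n_voxels[3], sum(st$bone_mask))
})
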