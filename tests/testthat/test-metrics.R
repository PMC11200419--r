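test_that("confusion counts match hand tallies", {
  n <- 9L
  empty <- array(FALSE, c(1, 3, 3))
  c0 <- confusion(empty, empty)
  expect_equal(c(c0$tp, c0$fp, c0$fn, c0$tn), c(0, 0, 0, n))
  # printed toy: pred 3 positives, truth 3, overlap 2
  pred <- mask_from_idx(c(1, 2, 3), c(1, 3, 3))
  truth <- mask_from_idx(c(2, 3, 4), c(1, 3, 3))
  ct <- confusion(pred, truth)
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(2, 1, 1, 5))
  samep <- confusion(pred, pred)
  expect_equal(c(samep$fp, samep$fn), c(0, 0))
  expect_error(confusion(pred, array(FALSE, c(1, 2, 2))), "shape")
})

test_that("smoothed Dice matches the formula, including the epsilon identity", {
  # empty-vs-empty with positive smoothing is exactly eps/eps = 1
  empty <- confusion(array(FALSE, c(2, 4, 4)), array(FALSE, c(2, 4, 4)))
  expect_identical(dice(empty, epsilon = 1e-6), 1)
  expect_identical(dice(empty, epsilon = 0.5), 1)
  # hand-checked 4/6
  toy <- list(tp = 2, fp = 1, fn = 1)
  expect_equal(dice(toy, epsilon = 0), 2 / 3)
  # undefined without smoothing
  expect_error(dice(empty, epsilon = 0), class = "bmelseg_dice_undefined")
  # perfect nonempty prediction scores 1 for any epsilon
  full <- list(tp = 10, fp = 0, fn = 0)
  for (eps in c(0, 1e-6, 1)) expect_equal(dice(full, eps), 1)
})

test_that("accuracy matches its formula and is inflated by true negatives", {
  expect_equal(accuracy(list(tp = 1, tn = 7, fp = 1, fn = 1)), 0.8)
  expect_equal(accuracy(list(tp = 5, tn = 0, fp = 0, fn = 0)), 1)
  base <- list(tp = 2, fp = 1, fn = 1, tn = 0)
  more_tn <- list(tp = 2, fp = 1, fn = 1, tn = 1000)
  expect_equal(dice(base, 0), dice(more_tn, 0))
  expect_gt(accuracy(more_tn), accuracy(base))
})

test_that("Dice is symmetric, bounded, and epsilon-continuous (property sweep)", {
  withr::with_seed(99, {
    for (i in 1:50) {
      d <- c(1L, sample(3:6, 2, replace = TRUE))
      a <- array(runif(prod(d)) < runif(1), d)
      b <- array(runif(prod(d)) < runif(1), d)
      eps <- sample(c(1e-6, 0.01, 1), 1)
      dab <- dice(confusion(a, b), eps)
      expect_identical(dab, dice(confusion(b, a), eps))
      expect_gte(dab, 0)
      expect_lte(dab, 1)
      ct <- confusion(a, b)
      if (2 * ct$tp + ct$fp + ct$fn > 0) {
        expect_equal(dice(ct, 1e-12), dice(ct, 0), tolerance = 1e-9)
      }
    }
  })
})

test_that("3D Dice equals the flatten-and-count oracle and ignores empty slices", {
  withr::with_seed(7, {
    a <- array(runif(4 * 5 * 5) < 0.3, c(4, 5, 5))
    b <- array(runif(4 * 5 * 5) < 0.3, c(4, 5, 5))
  })
  expect_equal(dice3d(a, b, 0), dice_oracle(a, b, 0))
  expect_equal(dice3d(a, a, 0), 1)
  disjoint <- mask_from_idx(1, c(1, 4, 4))
  other <- mask_from_idx(2, c(1, 4, 4))
  expect_equal(dice3d(disjoint, other, 0), 0)
  # appending mutually empty slices leaves 3D Dice unchanged
  a2 <- array(FALSE, c(6, 5, 5)); a2[1:4, , ] <- a
  b2 <- array(FALSE, c(6, 5, 5)); b2[1:4, , ] <- b
  expect_equal(dice3d(a2, b2, 0), dice3d(a, b, 0))
})

test_that("2D aggregation exposes the empty-slice skew that 3D avoids", {
  # 4-slice volume: two slices empty in both masks, two with Dice 1/2
  pred <- array(FALSE, c(4, 4, 4))
  truth <- array(FALSE, c(4, 4, 4))
  for (s in 1:2) {
    pred[s, 1, 1:2] <- TRUE       # 2 positives
    truth[s, 1, 2:3] <- TRUE      # 2 positives, overlap 1 -> Dice 0.5
  }
  all_slices <- dice2d(pred, truth, epsilon = 1e-6, scope = "all_slices")
  lesion_only <- dice2d(pred, truth, epsilon = 1e-6, scope = "lesion_slices")
  expect_equal(lesion_only, 0.5, tolerance = 1e-5)
  expect_equal(all_slices, 0.75, tolerance = 1e-5)  # empty slices score 1
  expect_gt(all_slices, lesion_only)
  # 3D Dice is immune to the same padding
  expect_equal(dice3d(pred, truth, 0),
               dice3d(pred[1:2, , , drop = FALSE], truth[1:2, , , drop = FALSE], 0))
  # epsilon = 0 policies for undefined slices
  expect_equal(dice2d(pred, truth, epsilon = 0, policy = "skip"), 0.5)
  expect_equal(dice2d(pred, truth, epsilon = 0, policy = "include_as_one"), 0.75)
  # lesion-slices scope requires at least one lesion-bearing slice
  none <- array(FALSE, c(2, 4, 4))
  expect_error(dice2d(none, none, scope = "lesion_slices"),
               class = "bmelseg_no_lesion_slices")
})

test_that("model evaluation averages volumes first, then raters", {
  dims <- c(1L, 4L, 4L)
  # volume 1: prediction {1,2}; raters score 1.0 and 0.8 against it
  p1 <- mask_from_idx(c(1, 2), dims)
  v1_r1 <- mask_from_idx(c(1, 2), dims)            # Dice 1.0
  v1_r2 <- mask_from_idx(c(1, 2, 3), dims)         # Dice 0.8
  # volume 2: prediction {1,2,3}; raters score 0.5 and 0.6
  p2 <- mask_from_idx(c(1, 2, 3), dims)
  v2_r1 <- mask_from_idx(c(1, 2, 4, 5, 6), dims)   # TP2 FP1 FN3 -> 0.5
  v2_r2 <- mask_from_idx(c(1, 2, 3, 4, 5, 6, 7), dims)  # TP3 FN4 -> 0.6
  ev <- evaluate_model(list(p1, p2),
                       list(list(r1 = v1_r1, r2 = v1_r2),
                            list(r1 = v2_r1, r2 = v2_r2)),
                       epsilon = 0)
  expect_equal(ev$mean_dice, c(0.75, 0.7))
  expect_equal(attr(ev, "overall"), 0.725)
  expect_equal(glance(ev)$overall_dice, 0.725)

  single <- evaluate_model(list(p1), list(list(r1 = v1_r2)), epsilon = 0)
  expect_equal(attr(single, "overall"), 0.8)
  dup <- evaluate_model(list(p1), list(list(a = v1_r2, b = v1_r2)), epsilon = 0)
  expect_equal(attr(dup, "overall"), 0.8)
  expect_error(evaluate_model(list(p1, p2), list(list(v1_r1))), "rater")
})

test_that("reliability report separates intra- from inter-rater agreement", {
  st <- generate_study(small_phantom(), seed = 71)
  truth_set <- list(rater = "A", set = 1, masks = list(st$lesion_truth))
  dup_set <- list(rater = "A", set = 2, masks = list(st$lesion_truth))
  rel <- reliability_report(list(truth_set, dup_set), epsilon = 1e-6)
  expect_equal(rel$type, "intra_rater")
  expect_equal(rel$dice_3d, 1)
  expect_equal(rel$dice_2d_all, 1)

  # zero-jitter raters agree perfectly across raters too
  zero <- list(threshold_sd = 0, morph_max = 0L, miss_prob = 0)
  r1 <- list(rater = "A", set = 1,
             masks = list(simulate_rater(st, zero, seed = 1)))
  r2 <- list(rater = "B", set = 1,
             masks = list(simulate_rater(st, zero, seed = 2)))
  rel2 <- reliability_report(list(r1, r2))
  expect_equal(rel2$type, "inter_rater")
  expect_equal(rel2$dice_3d, 1)
})

test_that("repeat annotations agree more than annotations across raters", {
  # each rater has a persistent threshold bias; repeats jitter around it.
  # a soft lesion rim (wide blur) makes threshold differences visible.
  repeat_jitter <- function(bias) {
    list(threshold_sd = 0.02, morph_max = 0L, miss_prob = 0,
         threshold_bias = bias)
  }
  soft_rim <- small_phantom(boundary_blur_sigma = 1.6)
  gaps <- vapply(c(1, 2, 3), function(run_seed) {
    studies <- generate_dataset(soft_rim, 0, 7, seed = 1000 + run_seed)
    sets <- list(
      list(rater = "A", set = 1, masks = lapply(seq_along(studies), function(i)
        simulate_rater(studies[[i]], repeat_jitter(0.12), seed = run_seed * 100 + i))),
      list(rater = "A", set = 2, masks = lapply(seq_along(studies), function(i)
        simulate_rater(studies[[i]], repeat_jitter(0.12), seed = run_seed * 100 + 50 + i))),
      list(rater = "B", set = 1, masks = lapply(seq_along(studies), function(i)
        simulate_rater(studies[[i]], repeat_jitter(-0.12), seed = run_seed * 100 + 80 + i)))
    )
    rel <- reliability_report(sets)
    rel$dice_3d[rel$type == "intra_rater"] - rel$dice_3d[rel$type == "inter_rater"]
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})
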