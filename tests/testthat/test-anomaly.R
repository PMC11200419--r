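test_that("anomaly maps are the positive part of real minus fake", {
  real <- array(c(0.2, -0.5, 0.3, 0.1), c(1, 2, 2))
  fake <- array(c(0.1, 0.0, 0.3, 0.4), c(1, 2, 2))
  m <- compute_anomaly_map(real, fake)
  expect_equal(as.numeric(m$values), c(0.1, 0, 0, 0))
  expect_true(all(m$values >= 0))
  # identical volumes: all zeros
  z <- compute_anomaly_map(real, real)
  expect_equal(sum(z$values), 0)
  # role swap: zero wherever the original was positive
  swapped <- compute_anomaly_map(fake, real)
  expect_true(all(swapped$values[m$values > 0] == 0))
  expect_error(compute_anomaly_map(real, array(0, c(1, 3, 2))), "shape")
})

test_that("bone masking zeroes outside-bone voxels and can only help", {
  vals <- array(0, c(1, 4, 4))
  vals[1, 1, 1] <- 0.9   # inside bone (true lesion)
  vals[1, 4, 4] <- 0.8   # outside bone (false positive)
  bone <- array(FALSE, c(1, 4, 4)); bone[1, 1:2, 1:2] <- TRUE
  truth <- array(FALSE, c(1, 4, 4)); truth[1, 1, 1] <- TRUE
  m <- compute_anomaly_map(vals, array(0, c(1, 4, 4)))

  ones <- apply_bone_mask(m, array(TRUE, c(1, 4, 4)))
  expect_equal(ones$values, m$values)
  zeros <- apply_bone_mask(m, array(FALSE, c(1, 4, 4)))
  expect_equal(sum(zeros$values), 0)

  masked <- apply_bone_mask(m, bone)
  expect_equal(masked$values[1, 4, 4], 0)
  expect_equal(masked$values[1, 1, 1], 0.9)
  d_before <- dice_oracle(binarize(m, 0.5), truth)
  d_after <- dice_oracle(binarize(masked, 0.5), truth)
  expect_gt(d_after, d_before)
})

test_that("binarization is a strict threshold", {
  vals <- array(0.1, c(2, 3, 3))
  lesion <- array(FALSE, c(2, 3, 3)); lesion[1, 1:2, 1:2] <- TRUE
  vals[lesion] <- 0.9
  m <- compute_anomaly_map(vals, array(0, dim(vals)))
  expect_identical(binarize(m, 0.5), lesion)
  expect_equal(sum(binarize(m, Inf)), 0L)
  # zeros stay negative under a negative threshold only via strictness
  z <- compute_anomaly_map(array(0, c(1, 2, 2)), array(0, c(1, 2, 2)))
  expect_equal(sum(binarize(z, 0)), 0L)
  expect_equal(sum(binarize(z, -0.1)), 4L)
})

test_that("threshold sweeps trace the Dice curve and average raters correctly", {
  vals <- array(0.1, c(2, 4, 4))
  lesion <- array(FALSE, c(2, 4, 4)); lesion[1, 1:2, 1:2] <- TRUE
  vals[lesion] <- 0.9
  m <- compute_anomaly_map(vals, array(0, dim(vals)))

  one <- sweep_thresholds(list(m), list(list(lesion)), grid = 0.5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_dice, 1, tolerance = 1e-5)
  expect_equal(select_threshold(one), 0.5)

  grid <- seq(0, 1, by = 0.02)
  sw <- sweep_thresholds(list(m), list(list(lesion)), grid)
  plateau <- sw$tau > 0.1 & sw$tau < 0.9
  expect_true(all(sw$mean_dice[plateau] > 1 - 1e-5))
  expect_true(all(sw$mean_dice[sw$tau >= 0.9] < 1))
  # duplicated rater leaves the curve unchanged
  sw2 <- sweep_thresholds(list(m), list(list(lesion, lesion)), grid)
  expect_equal(sw2$mean_dice, sw$mean_dice)
  expect_error(sweep_thresholds(list(m), list(list(lesion)), numeric()), "empty")
})

test_that("chosen thresholds equal a brute-force argmax with smallest-tau ties", {
  withr::with_seed(55, {
    maps <- lapply(1:4, function(i) {
      compute_anomaly_map(array(runif(2 * 5 * 5), c(2, 5, 5)),
                          array(0, c(2, 5, 5)))
    })
    raters <- lapply(1:4, function(i) {
      list(array(runif(2 * 5 * 5) < 0.3, c(2, 5, 5)),
           array(runif(2 * 5 * 5) < 0.3, c(2, 5, 5)))
    })
  })
  grid <- seq(0, 1, by = 0.05)
  sw <- sweep_thresholds(maps, raters, grid, epsilon = 1e-6)
  # independent brute force: plain loops and sums
  brute <- vapply(grid, function(tau) {
    per_rater <- vapply(1:2, function(r) {
      mean(vapply(1:4, function(v) {
        dice_oracle(maps[[v]]$values > tau, raters[[v]][[r]], 1e-6)
      }, numeric(1)))
    }, numeric(1))
    mean(per_rater)
  }, numeric(1))
  expect_equal(sw$mean_dice, brute)
  expect_equal(select_threshold(sw), grid[which.max(brute)])
  # explicit tie: flat curve picks the smallest tau
  flat <- tibble::tibble(tau = c(0.1, 0.2, 0.3), mean_dice = c(0.7, 0.7, 0.7))
  class(flat) <- c("threshold_sweep", class(flat))
  expect_equal(select_threshold(flat), 0.1)
})

test_that("three-fold threshold CV is exchangeable, reproducible, and averages folds", {
  vals <- array(0.1, c(2, 4, 4))
  lesion <- array(FALSE, c(2, 4, 4)); lesion[1, 1:2, 1:2] <- TRUE
  vals[lesion] <- 0.9
  m <- compute_anomaly_map(vals, array(0, dim(vals)))
  clones <- list(m, m, m, m, m, m)
  rmasks <- rep(list(list(lesion)), 6)
  cv <- threshold_cv(clones, rmasks, seed = 5)
  expect_equal(length(unique(cv$folds$tau)), 1L)
  expect_equal(cv$mean_dice, cv$folds$dice[1], tolerance = 1e-12)

  cv2 <- threshold_cv(clones, rmasks, seed = 5)
  expect_identical(cv$assignments, cv2$assignments)
  cv3 <- threshold_cv(clones, rmasks, seed = 6)
  expect_false(identical(cv$assignments, cv3$assignments))

  # reported mean equals the hand-average of the fold scores
  fx <- oracle_maps_fixture()
  cv6 <- threshold_cv(fx$maps, fx$raters, seed = 2)
  expect_equal(cv6$mean_dice, mean(cv6$folds$dice))
  expect_equal(tidy(cv6), cv6$folds)
  expect_equal(glance(cv6)$n_volumes, 6L)

  expect_error(threshold_cv(clones[1:2], rmasks[1:2]), "at least 3")
})
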