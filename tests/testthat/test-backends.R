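test_that("convolution and upsampling backward passes match finite differences", {
  withr::with_seed(3, {
    H <- 6L; W <- 5L; cin <- 2L; cout <- 3L
    X <- matrix(rnorm(H * W * cin), H * W, cin)
    for (stride in c(1L, 2L)) {
      plan <- bmelseg:::conv_plan(H, W, 3L, stride)
      Wm <- matrix(rnorm(9 * cin * cout, sd = 0.3), 9 * cin, cout)
      b <- rnorm(cout)
      loss <- function(Xv, Wv, bv) {
        sum(bmelseg:::conv_fwd(matrix(Xv, H * W, cin),
                               matrix(Wv, 9 * cin, cout), bv, plan)$Y^2) / 2
      }
      fw <- bmelseg:::conv_fwd(X, Wm, b, plan)
      bk <- bmelseg:::conv_bwd(fw$Y, fw$col, Wm, plan, cin)
      eps <- 1e-6
      for (i in sample(length(X), 4)) {
        X2 <- X; X2[i] <- X2[i] + eps
        expect_equal(bk$dX[i], (loss(X2, Wm, b) - loss(X, Wm, b)) / eps,
                     tolerance = 1e-3)
      }
      for (i in sample(length(Wm), 4)) {
        W2 <- Wm; W2[i] <- W2[i] + eps
        expect_equal(bk$dW[i], (loss(X, W2, b) - loss(X, Wm, b)) / eps,
                     tolerance = 1e-3)
      }
    }
    # upsample adjointness: <up(x), y> == <x, up_bwd(y)>
    u <- bmelseg:::upsample_plan(4L, 3L)
    x <- matrix(rnorm(12 * 2), 12, 2)
    y <- matrix(rnorm(48 * 2), 48, 2)
    expect_equal(sum(bmelseg:::upsample_fwd(x, u) * y),
                 sum(x * bmelseg:::upsample_bwd(y, u)))
  })
})

test_that("cGAN losses match their closed forms", {
  # hand-computed mean absolute error: (|1-0| + |2-4|) / 2 = 1.5
  gl <- cgan_generator_loss(d_out_fake = c(0.5, 0.5), x = c(1, 2),
                            x_hat = c(0, 4), lambda_l1 = 1)
  expect_equal(gl$l1, 1.5)
  expect_equal(gl$adversarial, log(2))
  expect_equal(gl$loss, log(2) + 1.5)
  # perfect reconstruction zeroes the L1 term
  expect_equal(cgan_generator_loss(0.5, c(1, 2), c(1, 2), 100)$l1, 0)
  # lambda 0: pure adversarial objective
  g0 <- cgan_generator_loss(c(0.25), c(1), c(9), lambda_l1 = 0)
  expect_equal(g0$loss, -log(0.25))

  # indifferent discriminator: 2 ln 2
  expect_equal(cgan_discriminator_loss(0.5, 0.5), 2 * log(2))
  # perfect discrimination drives the loss to 0
  expect_lt(cgan_discriminator_loss(1 - 1e-9, 1e-9), 1e-6)
  # label-swap symmetry with complemented outputs
  pr <- c(0.8, 0.6); pf <- c(0.3, 0.1)
  expect_equal(cgan_discriminator_loss(pr, pf),
               cgan_discriminator_loss(1 - pf, 1 - pr))
})

test_that("short cGAN training beats its own initialization on held-out slices", {
  studies <- lapply(generate_dataset(small_phantom(), 3, 0, seed = 500),
                    preprocess_study)
  pairs <- build_training_set(studies[1:2], "sequence_translation")
  held <- build_training_set(studies[3], "sequence_translation")
  l1_of <- function(bk) {
    mean(vapply(held, function(p) {
      mean(abs(backend_synthesize(bk, p) - p$target))
    }, numeric(1)))
  }
  init <- backend_train(cgan_backend(cgan_config(steps = 0L)), pairs, seed = 8)
  trained <- backend_train(cgan_backend(cgan_config(steps = 60L)), pairs, seed = 8)
  expect_lt(l1_of(trained), l1_of(init))
  # synthesis is deterministic and in range
  s1 <- backend_synthesize(trained, held[[1]])
  s2 <- backend_synthesize(trained, held[[1]])
  expect_identical(s1, s2)
  expect_equal(dim(s1), dim(held[[1]]$conditioning))
  expect_true(all(s1 >= -1 & s1 <= 1))
  expect_error(backend_synthesize(cgan_backend(), held[[1]]), "untrained")
})

test_that("oracle backend reproduces the healthy reference exactly", {
  fx <- oracle_maps_fixture()
  st <- fx$studies[[1]]
  backend <- oracle_backend(fx$studies)
  pr <- build_pair(st, 3L, "sequence_translation")
  expect_identical(backend_synthesize(backend, pr), st$healthy_target[3, , ])
  # differences confined to lesion support
  fake <- synthesize_healthy(backend, st, "sequence_translation")
  differs <- abs(st$target - fake) > 0
  expect_true(all(st$lesion_field[differs] > 0))
  # healthy study: anomaly map identically zero
  healthy <- preprocess_study(
    generate_study(oracle_phantom(), seed = 9, with_lesions = FALSE)
  )
  ob <- oracle_backend(list(healthy))
  fh <- synthesize_healthy(ob, healthy, "sequence_translation")
  expect_equal(max(compute_anomaly_map(healthy$target, fh)$values), 0)
  # unknown identity is an explicit error
  missing <- build_pair(st, 3L, "sequence_translation")
  missing$study_id <- "nope"
  expect_error(backend_synthesize(backend, missing),
               class = "bmelseg_oracle_miss")
})

test_that("all three backends drive the downstream framework (contract test)", {
  cfg <- phantom_config(grid_shape = c(8L, 16L, 16L), lesion_radius_range = c(3, 5),
                        noise_sd = 0.01)
  run <- run_pipeline(
    backends = c("oracle", "cgan", "diffusion"),
    tasks = "sequence_translation",
    phantom = cfg, n_train = 2L, n_test = 3L,
    annotations = "truth",
    cgan = cgan_config(width = 2L, steps = 30L, batch_size = 2L),
    diffusion = diffusion_config(timesteps = 15L, steps = 30L, width = 4L,
                                 batch_size = 2L),
    seed = 303
  )
  expect_equal(nrow(run$report), 3L)
  expect_true(all(run$report$mean_dice >= 0 & run$report$mean_dice <= 1))
  expect_setequal(run$report$backend, c("oracle", "cgan", "diffusion"))
  td <- tidy(run)
  expect_equal(nrow(td), 9L)  # 3 backends x 3 folds
  expect_true(all(c("backend", "task", "folds_tau", "folds_dice") %in% names(td)))
  expect_equal(nrow(glance(run)), 1L)
})
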