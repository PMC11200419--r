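#' Conditional GAN configuration
#'
#' Desk-scale Pix2Pix-style setup: a small U-Net generator with a final
#' hyperbolic-tangent activation and a patch-based convolutional
#' discriminator with three convolutional layers. The generator's latent
#' noise is realised implicitly through dropout, the usual Pix2Pix
#' convention, rather than an explicit noise input.
#'
#' @param width base channel width of the generator.
#' @param lambda_l1 weight of the L1 reconstruction term (Pix2Pix
#'   convention 100).
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param steps number of optimizer steps for [backend_train()].
#' @param init `"gaussian"` (default), `"kaiming"`, or `"zeros"`.
#' @param dropout dropout probability applied at the generator bottleneck
#'   during training.
#' @param n_layers discriminator convolutional layer count (fixed
#'   implementation uses 3; retained for the record).
#' @param out_range intensity range of inputs/outputs.
#' @return a `cgan_config` list.
#' @export
cgan_config <- function(width = 4L, lambda_l1 = 100, learning_rate = 2e-3,
                        batch_size = 4L, steps = 200L, init = "gaussian",
                        dropout = 0.5, n_layers = 3L, out_range = c(-1, 1)) {
  if (lambda_l1 < 0) abort_bmel("lambda_l1 must be >= 0")
  if (n_layers < 1L) abort_bmel("n_layers must be >= 1")
  structure(
    list(width = as.integer(width), lambda_l1 = lambda_l1,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         steps = as.integer(steps), init = init, dropout = dropout,
         n_layers = as.integer(n_layers), out_range = as.numeric(out_range)),
    class = "cgan_config"
  )
}

#' Full-scale reference configuration for the conditional GAN
#'
#' The configuration reported for the full-size clinical model: batch size
#' 36, Adam with fixed learning rate 5e-4, parameters initialised to zero,
#' PatchGAN discriminator with three convolutional layers. Desk-scale runs
#' use [cgan_config()] defaults instead.
#' @export
cgan_config_paper_scale <- function() {
  cgan_config(width = 64L, lambda_l1 = 100, learning_rate = 5e-4,
              batch_size = 36L, steps = 10000L, init = "zeros")
}

cgan_plans <- function(H, W) {
  list(
    p1 = conv_plan(H, W, 3L, 1L),
    p2 = conv_plan(H, W, 3L, 2L),
    p3 = conv_plan(H %/% 2L, W %/% 2L, 3L, 1L),
    up = upsample_plan(H %/% 2L, W %/% 2L),
    p4 = conv_plan(H, W, 3L, 1L),
    d1 = conv_plan(H, W, 3L, 2L),
    d2 = conv_plan(H %/% 2L, W %/% 2L, 3L, 2L),
    d3 = conv_plan(H %/% 4L, W %/% 4L, 3L, 1L)
  )
}

cgan_init_params <- function(config) {
  w <- config$width
  ini <- config$init
  g <- list(
    W1 = init_conv(3L, 1L, w, ini), W2 = init_conv(3L, w, 2L * w, ini),
    W3 = init_conv(3L, 2L * w, 2L * w, ini), W4 = init_conv(3L, 3L * w, 1L, ini)
  )
  d <- list(
    V1 = init_conv(3L, 2L, w, ini), V2 = init_conv(3L, w, 2L * w, ini),
    V3 = init_conv(3L, 2L * w, 1L, ini)
  )
  flat <- function(lst) {
    out <- list()
    for (nm in names(lst)) {
      out[[paste0(nm, "_W")]] <- lst[[nm]]$W
      out[[paste0(nm, "_b")]] <- lst[[nm]]$b
    }
    out
  }
  list(g = flat(g), d = flat(d))
}

# Generator forward pass. `drop_mask` (same shape as the bottleneck
# activation) realises dropout during training; NULL disables it.
g_forward <- function(pg, c_img, plans, drop_mask = NULL) {
  X <- matrix(as.numeric(c_img), ncol = 1L)
  f1 <- conv_fwd(X, pg$W1_W, pg$W1_b, plans$p1)
  h1 <- lrelu(f1$Y)
  f2 <- conv_fwd(h1, pg$W2_W, pg$W2_b, plans$p2)
  h2 <- lrelu(f2$Y)
  f3 <- conv_fwd(h2, pg$W3_W, pg$W3_b, plans$p3)
  h3 <- lrelu(f3$Y)
  if (!is.null(drop_mask)) h3 <- h3 * drop_mask
  u <- upsample_fwd(h3, plans$up)
  cat_ <- cbind(u, h1)
  f4 <- conv_fwd(cat_, pg$W4_W, pg$W4_b, plans$p4)
  y <- tanh(f4$Y)
  list(y = y, X = X, f1 = f1, f2 = f2, f3 = f3, f4 = f4,
       h1 = h1, h2 = h2, h3 = h3, cat_ = cat_, drop_mask = drop_mask)
}

# Backprop through the generator given dL/dy. Returns parameter grads.
g_backward <- function(pg, fw, dy, plans, width) {
  da4 <- dy * (1 - fw$y^2)
  b4 <- conv_bwd(da4, fw$f4$col, pg$W4_W, plans$p4, 3L * width)
  dcat <- b4$dX
  du <- dcat[, seq_len(2L * width), drop = FALSE]
  dh1_skip <- dcat[, 2L * width + seq_len(width), drop = FALSE]
  dh3 <- upsample_bwd(du, plans$up)
  if (!is.null(fw$drop_mask)) dh3 <- dh3 * fw$drop_mask
  da3 <- dh3 * lrelu_grad(fw$f3$Y)
  b3 <- conv_bwd(da3, fw$f3$col, pg$W3_W, plans$p3, 2L * width)
  da2 <- b3$dX * lrelu_grad(fw$f2$Y)
  b2 <- conv_bwd(da2, fw$f2$col, pg$W2_W, plans$p2, width)
  dh1 <- b2$dX + dh1_skip
  da1 <- dh1 * lrelu_grad(fw$f1$Y)
  b1 <- conv_bwd(da1, fw$f1$col, pg$W1_W, plans$p1, 1L)
  list(W1_W = b1$dW, W1_b = b1$db, W2_W = b2$dW, W2_b = b2$db,
       W3_W = b3$dW, W3_b = b3$db, W4_W = b4$dW, W4_b = b4$db)
}

# Discriminator forward on a (conditioning, candidate target) pair.
d_forward <- function(pd, c_img, x_img, plans) {
  X <- cbind(as.numeric(c_img), as.numeric(x_img))
  f1 <- conv_fwd(X, pd$V1_W, pd$V1_b, plans$d1)
  h1 <- lrelu(f1$Y)
  f2 <- conv_fwd(h1, pd$V2_W, pd$V2_b, plans$d2)
  h2 <- lrelu(f2$Y)
  f3 <- conv_fwd(h2, pd$V3_W, pd$V3_b, plans$d3)
  p <- sigmoid(f3$Y)
  list(p = p, logits = f3$Y, f1 = f1, f2 = f2, f3 = f3)
}

# Backprop through the discriminator given dL/dlogits; also returns the
# gradient with respect to the candidate-target input channel (needed for
# the generator's adversarial gradient).
d_backward <- function(pd, fw, dlogits, plans, width) {
  b3 <- conv_bwd(dlogits, fw$f3$col, pd$V3_W, plans$d3, 2L * width)
  da2 <- b3$dX * lrelu_grad(fw$f2$Y)
  b2 <- conv_bwd(da2, fw$f2$col, pd$V2_W, plans$d2, width)
  da1 <- b2$dX * lrelu_grad(fw$f1$Y)
  b1 <- conv_bwd(da1, fw$f1$col, pd$V1_W, plans$d1, 2L)
  list(
    grads = list(V1_W = b1$dW, V1_b = b1$db, V2_W = b2$dW, V2_b = b2$db,
                 V3_W = b3$dW, V3_b = b3$db),
    dx = b1$dX[, 2L]
  )
}

#' Generator loss: non-saturating adversarial term plus weighted L1
#'
#' The adversarial part is the non-saturating form
#' `-mean(log D(x_hat, c))`; the reconstruction part is the mean absolute
#' error between the real target and the synthesis, weighted by
#' `lambda_l1`, which discourages the blurring an L2 penalty would invite.
#'
#' @param d_out_fake discriminator probabilities on the synthesized pair.
#' @param x real target image.
#' @param x_hat synthesized image.
#' @param lambda_l1 L1 weight.
#' @return list with `loss`, `adversarial`, and (unweighted) `l1`.
#' @export
cgan_generator_loss <- function(d_out_fake, x, x_hat, lambda_l1 = 100) {
  p <- pmin(pmax(d_out_fake, 1e-12), 1 - 1e-12)
  adv <- -mean(log(p))
  l1 <- mean(abs(x - x_hat))
  list(loss = adv + lambda_l1 * l1, adversarial = adv, l1 = l1)
}

#' Discriminator loss: binary cross-entropy on real and synthesized pairs
#'
#' `-mean(log D(x, c)) - mean(log(1 - D(x_hat, c)))`.
#'
#' @param d_out_real,d_out_fake discriminator probabilities.
#' @return scalar loss.
#' @export
cgan_discriminator_loss <- function(d_out_real, d_out_fake) {
  pr <- pmin(pmax(d_out_real, 1e-12), 1 - 1e-12)
  pf <- pmin(pmax(d_out_fake, 1e-12), 1 - 1e-12)
  -mean(log(pr)) - mean(log(1 - pf))
}

#' Construct an (untrained) conditional GAN backend
#'
#' @param config a [cgan_config()].
#' @return object of class `c("cgan_backend", "bmel_backend")`.
#' @export
cgan_backend <- function(config = cgan_config()) {
  structure(
    list(config = config, trained = FALSE, params = NULL, curve = NULL),
    class = c("cgan_backend", "bmel_backend")
  )
}

#' @rdname backend_train
#' @export
backend_train.cgan_backend <- function(backend, pairs, seed = 1L, ...) {
  cfg <- backend$config
  H <- nrow(pairs[[1]]$conditioning)
  W <- ncol(pairs[[1]]$conditioning)
  plans <- cgan_plans(H, W)
  width <- cfg$width
  n_bneck <- plans$p3$npo
  curve <- vector("list", cfg$steps)
  params <- with_seed(seed, {
    prm <- cgan_init_params(cfg)
    opt_g <- adam_init(prm$g)
    opt_d <- adam_init(prm$d)
    for (step in seq_len(cfg$steps)) {
      take <- sample.int(length(pairs), cfg$batch_size,
                         replace = length(pairs) < cfg$batch_size)
      # --- discriminator update ---
      gd <- NULL
      d_loss <- 0
      for (i in take) {
        pr <- pairs[[i]]
        dm <- if (cfg$dropout > 0) {
          matrix(rbinom(n_bneck * 2L * width, 1L, 1 - cfg$dropout),
                 n_bneck, 2L * width) / (1 - cfg$dropout)
        }
        gfw <- g_forward(prm$g, pr$conditioning, plans, dm)
        dr <- d_forward(prm$d, pr$conditioning, pr$target, plans)
        df <- d_forward(prm$d, pr$conditioning, gfw$y, plans)
        d_loss <- d_loss + cgan_discriminator_loss(dr$p, df$p)
        np <- length(dr$p)
        br <- d_backward(prm$d, dr, (dr$p - 1) / np, plans, width)
        bf <- d_backward(prm$d, df, df$p / np, plans, width)
        gd <- add_grads(gd, add_grads(br$grads, bf$grads))
      }
      sd_ <- adam_step(opt_d, prm$d, scale_grads(gd, 1 / cfg$batch_size),
                       cfg$learning_rate)
      opt_d <- sd_$opt; prm$d <- sd_$params
      # --- generator update (against the updated discriminator) ---
      gg <- NULL
      g_loss <- 0; l1_loss <- 0
      for (i in take) {
        pr <- pairs[[i]]
        dm <- if (cfg$dropout > 0) {
          matrix(rbinom(n_bneck * 2L * width, 1L, 1 - cfg$dropout),
                 n_bneck, 2L * width) / (1 - cfg$dropout)
        }
        gfw <- g_forward(prm$g, pr$conditioning, plans, dm)
        df <- d_forward(prm$d, pr$conditioning, gfw$y, plans)
        ls <- cgan_generator_loss(df$p, as.numeric(pr$target), gfw$y,
                                  cfg$lambda_l1)
        g_loss <- g_loss + ls$loss; l1_loss <- l1_loss + ls$l1
        np <- length(df$p)
        badv <- d_backward(prm$d, df, (df$p - 1) / np, plans, width)
        x_vec <- as.numeric(pr$target)
        dl1 <- cfg$lambda_l1 * sign(gfw$y - x_vec) / length(x_vec)
        dy <- matrix(badv$dx + dl1, ncol = 1L)
        gg <- add_grads(gg, g_backward(prm$g, gfw, dy, plans, width))
      }
      sg_ <- adam_step(opt_g, prm$g, scale_grads(gg, 1 / cfg$batch_size),
                       cfg$learning_rate)
      opt_g <- sg_$opt; prm$g <- sg_$params
      curve[[step]] <- tibble::tibble(
        step = step, d_loss = d_loss / cfg$batch_size,
        g_loss = g_loss / cfg$batch_size, l1 = l1_loss / cfg$batch_size
      )
    }
    prm
  })
  backend$params <- params
  backend$H <- H; backend$W <- W
  backend$plans <- plans
  backend$curve <- dplyr::bind_rows(curve)
  backend$trained <- TRUE
  backend$seed <- as.integer(seed)
  backend
}

#' @rdname backend_synthesize
#' @export
backend_synthesize.cgan_backend <- function(backend, pair, ...) {
  if (!isTRUE(backend$trained)) abort_bmel("cGAN backend is untrained")
  c_img <- pair$conditioning
  fw <- g_forward(backend$params$g, c_img, backend$plans, drop_mask = NULL)
  r <- backend$config$out_range
  matrix(pmin(pmax(fw$y, r[1]), r[2]), nrow(c_img), ncol(c_img))
}

#' @importFrom stats rbinom
NULL
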