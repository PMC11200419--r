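#' Conditional diffusion model configuration
#'
#' A conditional denoising diffusion probabilistic model: the noise model
#' takes the noisy target concatenated with the undisturbed conditioning
#' image at every step, plus a sinusoidal timestep embedding. Training
#' minimises the L2 distance between sampled and predicted noise; no
#' additional reconstruction loss is used. The noise schedule is quadratic:
#' square of linearly spaced square roots between `beta_start` and
#' `beta_end`.
#'
#' @param timesteps number of diffusion steps T (desk default 100; the
#'   full-scale reference uses 1000).
#' @param beta_start,beta_end schedule endpoints, `0 < beta_start <=
#'   beta_end < 1`.
#' @param width channel width of the noise model.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param steps optimizer steps for [backend_train()].
#' @param init weight initialisation (`"kaiming"` default, fan-based).
#' @param emb_dim sinusoidal timestep embedding dimension (even).
#' @param out_range intensity range of the data.
#' @return a `diffusion_config` list.
#' @export
diffusion_config <- function(timesteps = 100L, beta_start = 1e-4,
                             beta_end = 0.02, width = 8L,
                             learning_rate = 1e-3, batch_size = 6L,
                             steps = 200L, init = "kaiming", emb_dim = 8L,
                             out_range = c(-1, 1)) {
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    abort_bmel("need 0 < beta_start <= beta_end < 1")
  }
  if (timesteps < 2L) abort_bmel("timesteps must be >= 2")
  if (emb_dim %% 2L != 0L) abort_bmel("emb_dim must be even")
  structure(
    list(timesteps = as.integer(timesteps), beta_start = beta_start,
         beta_end = beta_end, width = as.integer(width),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         steps = as.integer(steps), init = init, emb_dim = as.integer(emb_dim),
         out_range = as.numeric(out_range)),
    class = "diffusion_config"
  )
}

#' Full-scale reference configuration for the conditional diffusion model
#'
#' Batch size 6, Adam with fixed learning rate 1e-4, Kaiming
#' initialisation, quadratic noise schedule with 1000 timesteps.
#' @export
diffusion_config_paper_scale <- function() {
  diffusion_config(timesteps = 1000L, learning_rate = 1e-4,
                   batch_size = 6L, width = 64L, init = "kaiming")
}

#' Quadratic noise schedule
#'
#' `beta_t = (sqrt(beta_start) + (t-1)/(T-1) * (sqrt(beta_end) -
#' sqrt(beta_start)))^2` for `t = 1..T`. The cumulative products
#' `alpha_bar_t = prod_{s<=t}(1 - beta_s)` are strictly decreasing.
#'
#' @param timesteps T.
#' @param beta_start,beta_end endpoints.
#' @return list with `betas`, `alphas`, `alpha_bars` (class
#'   `noise_schedule`).
#' @export
quadratic_schedule <- function(timesteps, beta_start = 1e-4, beta_end = 0.02) {
  t <- seq_len(timesteps)
  betas <- (sqrt(beta_start) +
              (t - 1) / (timesteps - 1) * (sqrt(beta_end) - sqrt(beta_start)))^2
  alphas <- 1 - betas
  structure(
    list(betas = betas, alphas = alphas, alpha_bars = cumprod(alphas),
         timesteps = as.integer(timesteps)),
    class = "noise_schedule"
  )
}

#' Forward (noising) diffusion step
#'
#' `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * noise`.
#'
#' @param x0 clean data (any numeric array).
#' @param t timestep in `1..T`.
#' @param noise standard-normal array shaped like `x0`.
#' @param schedule a [quadratic_schedule()].
#' @return noised data, same shape as `x0`.
#' @export
diffusion_forward <- function(x0, t, noise, schedule) {
  if (t < 1L || t > schedule$timesteps) {
    abort_bmel("t = ", t, " outside 1..", schedule$timesteps)
  }
  if (length(noise) != length(x0)) abort_bmel("noise must be shaped like x0")
  ab <- schedule$alpha_bars[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * noise
}

# sinusoidal timestep embedding (row vector of length emb_dim)
time_embedding <- function(t, emb_dim) {
  half <- emb_dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(1L, half - 1L))
  c(sin(t * freqs), cos(t * freqs))
}

diffusion_init_params <- function(config) {
  w <- config$width
  ini <- config$init
  cv <- function(cin, cout) init_conv(3L, cin, cout, ini)
  dn <- init_dense(config$emb_dim, w, ini)
  list(
    C1_W = cv(2L, w)$W, C1_b = cv(2L, w)$b,
    T_W = dn$W, T_b = dn$b,
    C2_W = cv(w, w)$W, C2_b = cv(w, w)$b,
    C3_W = cv(w, 1L)$W, C3_b = cv(w, 1L)$b
  )
}

diffusion_plans <- function(H, W) {
  list(p = conv_plan(H, W, 3L, 1L))
}

# noise-model forward: x_t and c concatenated channelwise, timestep
# embedding added as a per-channel bias after the first convolution
eps_forward <- function(params, x_t, c_img, t, plans, emb_dim) {
  X <- cbind(as.numeric(x_t), as.numeric(c_img))
  emb <- time_embedding(t, emb_dim)
  temb <- as.numeric(emb %*% params$T_W) + params$T_b
  f1 <- conv_fwd(X, params$C1_W, params$C1_b, plans$p)
  a1 <- f1$Y + rep(temb, each = nrow(f1$Y))
  h1 <- lrelu(a1)
  f2 <- conv_fwd(h1, params$C2_W, params$C2_b, plans$p)
  h2 <- lrelu(f2$Y)
  f3 <- conv_fwd(h2, params$C3_W, params$C3_b, plans$p)
  list(out = f3$Y, X = X, emb = emb, a1 = a1, f1 = f1, f2 = f2, f3 = f3)
}

eps_backward <- function(params, fw, dout, plans, width) {
  b3 <- conv_bwd(dout, fw$f3$col, params$C3_W, plans$p, width)
  da2 <- b3$dX * lrelu_grad(fw$f2$Y)
  b2 <- conv_bwd(da2, fw$f2$col, params$C2_W, plans$p, width)
  da1 <- b2$dX * lrelu_grad(fw$a1)
  b1 <- conv_bwd(da1, fw$f1$col, params$C1_W, plans$p, 2L)
  dtemb <- colSums(da1)
  list(C1_W = b1$dW, C1_b = b1$db,
       T_W = outer(fw$emb, dtemb), T_b = dtemb,
       C2_W = b2$dW, C2_b = b2$db, C3_W = b3$dW, C3_b = b3$db)
}

#' One diffusion training step
#'
#' For each pair in the batch: draw a timestep and standard-normal noise,
#' noise the target, predict the noise from the (noisy target,
#' conditioning) pair, and apply one Adam step on the mean squared error
#' between sampled and predicted noise.
#'
#' @param pairs_batch list of `conditioning_pair`.
#' @param state diffusion training state (see [diffusion_backend()]).
#' @param config a [diffusion_config()].
#' @return list with updated `state` and scalar `loss`.
#' @export
diffusion_train_step <- function(pairs_batch, state, config = state$config) {
  grads <- NULL
  loss <- 0
  for (pr in pairs_batch) {
    t <- sample.int(config$timesteps, 1L)
    noise <- matrix(rnorm(length(pr$target)), nrow = length(pr$target))
    x0 <- matrix(as.numeric(pr$target), ncol = 1L)
    x_t <- diffusion_forward(x0, t, noise, state$schedule)
    fw <- eps_forward(state$params, x_t, pr$conditioning, t, state$plans,
                      config$emb_dim)
    resid <- fw$out - noise
    loss <- loss + mean(resid^2)
    dout <- 2 * resid / length(resid)
    grads <- add_grads(
      grads, eps_backward(state$params, fw, dout, state$plans, config$width)
    )
  }
  n <- length(pairs_batch)
  st <- adam_step(state$opt, state$params, scale_grads(grads, 1 / n),
                  config$learning_rate)
  state$opt <- st$opt
  state$params <- st$params
  list(state = state, loss = loss / n)
}

#' Construct an (untrained) conditional diffusion backend
#'
#' @param config a [diffusion_config()].
#' @return object of class `c("diffusion_backend", "bmel_backend")`.
#' @export
diffusion_backend <- function(config = diffusion_config()) {
  structure(
    list(config = config, trained = FALSE, state = NULL, curve = NULL),
    class = c("diffusion_backend", "bmel_backend")
  )
}

#' @rdname backend_train
#' @export
backend_train.diffusion_backend <- function(backend, pairs, seed = 1L, ...) {
  cfg <- backend$config
  H <- nrow(pairs[[1]]$conditioning)
  W <- ncol(pairs[[1]]$conditioning)
  curve <- vector("list", cfg$steps)
  state <- with_seed(seed, {
    st <- list(
      params = diffusion_init_params(cfg),
      schedule = quadratic_schedule(cfg$timesteps, cfg$beta_start, cfg$beta_end),
      plans = diffusion_plans(H, W),
      config = cfg, H = H, W = W
    )
    st$opt <- adam_init(st$params)
    for (step in seq_len(cfg$steps)) {
      take <- sample.int(length(pairs), cfg$batch_size,
                         replace = length(pairs) < cfg$batch_size)
      res <- diffusion_train_step(pairs[take], st, cfg)
      st <- res$state
      curve[[step]] <- tibble::tibble(step = step, loss = res$loss)
    }
    st
  })
  params <- state$params
  plans <- state$plans
  emb_dim <- cfg$emb_dim
  state$predict <- function(x_t, c_img, t) {
    eps_forward(params, x_t, c_img, t, plans, emb_dim)$out
  }
  backend$state <- state
  backend$curve <- dplyr::bind_rows(curve)
  backend$trained <- TRUE
  backend$seed <- as.integer(seed)
  backend$H <- H; backend$W <- W
  backend
}

#' Ancestral sampling from a trained conditional diffusion model
#'
#' Starts from standard-normal noise and iterates the reverse update from
#' `t = T` down to 1, passing the original undisturbed conditioning image
#' to the noise model at every step; no noise is added at the final step.
#' The output is clamped to the configured intensity range. Deterministic
#' for a fixed `(state, c_img, sampling_seed)`.
#'
#' @param c_img conditioning image (matrix).
#' @param state trained diffusion state: needs `predict(x_t, c, t)`,
#'   `schedule`, and `trained` is implied by `predict` being present.
#' @param config a [diffusion_config()].
#' @param sampling_seed integer seed.
#' @return matrix shaped like `c_img`.
#' @export
diffusion_sample <- function(c_img, state, config = state$config,
                             sampling_seed = 1L) {
  if (is.null(state$predict)) {
    abort_bmel("diffusion state is untrained (no predict function)")
  }
  sch <- state$schedule
  TT <- sch$timesteps
  n <- length(c_img)
  with_seed(sampling_seed, {
    x <- matrix(rnorm(n), ncol = 1L)
    for (t in TT:1L) {
      eps_hat <- state$predict(x, c_img, t)
      beta <- sch$betas[t]
      ab <- sch$alpha_bars[t]
      mu <- (x - beta / sqrt(1 - ab) * eps_hat) / sqrt(sch$alphas[t])
      if (t > 1L) {
        ab_prev <- sch$alpha_bars[t - 1L]
        sigma2 <- beta * (1 - ab_prev) / (1 - ab)
        x <- mu + sqrt(sigma2) * matrix(rnorm(n), ncol = 1L)
      } else {
        x <- mu
      }
    }
    r <- config$out_range
    matrix(pmin(pmax(x, r[1]), r[2]), nrow(c_img), ncol(c_img))
  })
}

#' @rdname backend_synthesize
#' @export
backend_synthesize.diffusion_backend <- function(backend, pair,
                                                 sampling_seed = NULL, ...) {
  if (!isTRUE(backend$trained)) abort_bmel("diffusion backend is untrained")
  if (is.null(sampling_seed)) {
    sampling_seed <- (backend$seed %||% 1L) * 131L + pair$slice_index
  }
  diffusion_sample(pair$conditioning, backend$state, backend$config,
                   sampling_seed = sampling_seed %% .Machine$integer.max)
}
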