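# Minimal convolutional-network toolkit.
#
# There is no deep-learning runtime in this package's dependency set, and
# the generative backends are the heart of the method, so the few layer
# types they need are implemented here directly on BLAS matrix products
# with analytic backpropagation. A 2D feature map is stored as a
# (H*W) x channels matrix with column-major pixel order (pixel index
# r + (c-1)*H), which makes "same"-padded convolution a gather followed by
# one matrix multiply (im2col).

# Precompute the im2col gather indices for a k x k convolution.
# Index n_in + 1 is the zero-padding slot.
conv_plan <- function(H, W, k = 3L, stride = 1L) {
  p <- (k - 1L) %/% 2L
  Ho <- (H + 2L * p - k) %/% stride + 1L
  Wo <- (W + 2L * p - k) %/% stride + 1L
  npo <- Ho * Wo
  io <- rep(seq_len(Ho), Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, npo, k * k)
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      m <- di + (dj - 1L) * k
      r <- (io - 1L) * stride + di - p
      c <- (jo - 1L) * stride + dj - p
      ok <- r >= 1L & r <= H & c >= 1L & c <= W
      idx[, m] <- ifelse(ok, r + (c - 1L) * H, H * W + 1L)
    }
  }
  list(idx = idx, H = H, W = W, Ho = Ho, Wo = Wo, npo = npo,
       n_in = H * W, k2 = k * k)
}

conv_fwd <- function(X, Wm, b, plan) {
  cin <- ncol(X)
  Xp <- rbind(X, 0)
  col <- Xp[as.vector(plan$idx), , drop = FALSE]
  dim(col) <- c(plan$npo, plan$k2 * cin)
  Y <- col %*% Wm
  Y <- Y + rep(b, each = plan$npo)
  list(Y = Y, col = col)
}

conv_bwd <- function(dY, col, Wm, plan, cin) {
  dW <- crossprod(col, dY)
  db <- colSums(dY)
  dcol <- dY %*% t(Wm)
  dim(dcol) <- c(plan$npo, plan$k2, cin)
  dXp <- matrix(0, plan$n_in + 1L, cin)
  for (m in seq_len(plan$k2)) {
    ii <- plan$idx[, m]
    ok <- ii <= plan$n_in
    if (!any(ok)) next
    dm <- dcol[, m, , drop = FALSE]
    dim(dm) <- c(plan$npo, cin)
    dXp[ii[ok], ] <- dXp[ii[ok], , drop = FALSE] + dm[ok, , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dXp[seq_len(plan$n_in), , drop = FALSE])
}

lrelu <- function(x, alpha = 0.2) ifelse(x > 0, x, alpha * x)
lrelu_grad <- function(x, alpha = 0.2) ifelse(x > 0, 1, alpha)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Nearest-neighbour x2 upsampling gather index for an H x W map.
upsample_plan <- function(H, W) {
  ro <- rep(seq_len(2L * H), 2L * W)
  co <- rep(seq_len(2L * W), each = 2L * H)
  ceiling(ro / 2) + (ceiling(co / 2) - 1L) * H
}

upsample_fwd <- function(X, uidx) X[uidx, , drop = FALSE]
upsample_bwd <- function(dY, uidx) rowsum(dY, uidx)

# Weight initialisation. "gaussian" is the pragmatic small-Gaussian
# default; "kaiming" is fan-in scaled for ReLU-family nets; "zeros" is
# exposed because it is a documented configuration of the full-scale model.
init_conv <- function(k, cin, cout, method = "gaussian") {
  n <- k * k * cin
  Wm <- switch(method,
    gaussian = matrix(rnorm(n * cout, sd = 0.05), n, cout),
    kaiming = matrix(rnorm(n * cout, sd = sqrt(2 / n)), n, cout),
    zeros = matrix(0, n, cout),
    abort_bmel("unknown init method '", method, "'")
  )
  list(W = Wm, b = numeric(cout))
}

init_dense <- function(nin, nout, method = "gaussian") {
  Wm <- switch(method,
    gaussian = matrix(rnorm(nin * nout, sd = 0.05), nin, nout),
    kaiming = matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
    zeros = matrix(0, nin, nout),
    abort_bmel("unknown init method '", method, "'")
  )
  list(W = Wm, b = numeric(nout))
}

# Adam optimizer over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(
    m = purrr::map(params, ~ array(0, dim(.x) %||% length(.x))),
    v = purrr::map(params, ~ array(0, dim(.x) %||% length(.x))),
    t = 0L
  )
}

adam_step <- function(opt, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mh <- opt$m[[nm]] / bc1
    vh <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(opt = opt, params = params)
}

# elementwise-add two grad lists with matching names
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) purrr::map(g, ~ .x * s)
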