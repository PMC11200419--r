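#' @importFrom stats quantile rnorm runif setNames sd
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
abort_bmel <- function(..., class = "bmelseg_error") {
  rlang::abort(paste0(...), class = class)
}

assert_volume <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort_bmel(name, " must be a 3D array")
  }
  if (!all(is.finite(x))) abort_bmel(name, " contains non-finite values")
  invisible(x)
}

assert_same_shape <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    abort_bmel(
      "shape mismatch between ", what, ": ",
      paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x")
    )
  }
  invisible(TRUE)
}

#' Run code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

#' Truncated separable Gaussian blur of a 3D array
#'
#' Kernel support is truncated at 3 sigma, so the blurred field of a
#' compactly supported input remains compactly supported (needed for the
#' exact healthy-equals-target-outside-lesions invariant of the phantom).
#' Zero padding at the edges.
#'
#' @param x 3D array, dims (slice, row, col).
#' @param sigma in-plane standard deviation in voxels.
#' @param sigma_slice through-plane standard deviation in voxels
#'   (slices are typically thicker; defaults to half of `sigma`).
#' @return blurred array of the same shape.
#' @keywords internal
blur3d <- function(x, sigma, sigma_slice = sigma / 2) {
  if (sigma <= 0 && sigma_slice <= 0) return(x)
  out <- x
  sig <- c(sigma_slice, sigma, sigma)
  for (ax in 1:3) {
    s <- sig[ax]
    if (s <= 0) next
    k <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-k:k, sd = s)
    w <- w / sum(w)
    out <- convolve_axis(out, w, ax)
  }
  out
}

# 1D convolution along one axis of a 3D array, zero-padded, by shifted adds.
convolve_axis <- function(x, w, axis) {
  d <- dim(x)
  n <- d[axis]
  k <- (length(w) - 1L) / 2L
  acc <- array(0, d)
  for (j in seq_along(w)) {
    off <- j - k - 1L            # offset in -k..k
    src <- seq_len(n) + off      # source index per output index
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    idx_out <- which(ok)
    idx_src <- src[ok]
    if (axis == 1L) {
      acc[idx_out, , ] <- acc[idx_out, , ] + w[j] * x[idx_src, , , drop = FALSE]
    } else if (axis == 2L) {
      acc[, idx_out, ] <- acc[, idx_out, ] + w[j] * x[, idx_src, , drop = FALSE]
    } else {
      acc[, , idx_out] <- acc[, , idx_out] + w[j] * x[, , idx_src, drop = FALSE]
    }
  }
  acc
}

#' In-plane binary dilation/erosion with a square structuring element
#'
#' Operates slice-by-slice (annotations are drawn per sagittal slice).
#' `radius > 0` dilates, `radius < 0` erodes, `0` is the identity.
#' @keywords internal
morph2d <- function(mask, radius) {
  if (radius == 0) return(mask)
  erode <- radius < 0
  r <- abs(radius)
  d <- dim(mask)
  m <- array(as.numeric(mask), d)
  # separable box min/max via shifted comparisons
  for (ax in 2:3) {
    acc <- m
    n <- d[ax]
    for (off in setdiff(-r:r, 0L)) {
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      idx_out <- which(ok)
      idx_src <- src[ok]
      shifted <- array(if (erode) 1 else 0, d)
      if (ax == 2L) {
        shifted[, idx_out, ] <- m[, idx_src, , drop = FALSE]
      } else {
        shifted[, , idx_out] <- m[, , idx_src, drop = FALSE]
      }
      acc <- if (erode) pmin(acc, shifted) else pmax(acc, shifted)
    }
    m <- acc
  }
  array(m > 0.5, d)
}

#' 3D binary erosion with a small box element (used to keep lesion seeds
#' away from the bone boundary).
#' @keywords internal
erode3d <- function(mask, radius) {
  if (radius <= 0) return(array(as.logical(mask), dim(mask)))
  m <- array(as.numeric(mask), dim(mask))
  d <- dim(mask)
  for (ax in 1:3) {
    r <- if (ax == 1L) min(radius, 1L) else radius
    if (r <= 0) next
    acc <- m
    n <- d[ax]
    for (off in setdiff(-r:r, 0L)) {
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      idx_out <- which(ok)
      idx_src <- src[ok]
      shifted <- array(1, d)
      if (ax == 1L) {
        shifted[idx_out, , ] <- m[idx_src, , , drop = FALSE]
      } else if (ax == 2L) {
        shifted[, idx_out, ] <- m[, idx_src, , drop = FALSE]
      } else {
        shifted[, , idx_out] <- m[, , idx_src, drop = FALSE]
      }
      acc <- pmin(acc, shifted)
    }
    m <- acc
  }
  array(m > 0.5, d)
}
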