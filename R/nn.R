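# Minimal convolutional building blocks used by the WGAN-GP harmonizer.
# Feature maps are (H, W, C) arrays; conv weights are (C_in * k * k, C_out)
# matrices matching the cpp_im2col column layout, with per-output-channel bias.

conv_param <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       init_sd = sqrt(2 / (c_in * k * k))) {
  W <- matrix(rnorm(c_in * k * k * c_out, sd = init_sd), c_in * k * k, c_out)
  list(W = W, b = numeric(c_out), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), c_in = as.integer(c_in), c_out = as.integer(c_out))
}

conv_forward <- function(x, p, W = p$W) {
  d <- dim(x)
  cols <- cpp_im2col(as.numeric(x), d[1], d[2], d[3], p$k, p$stride, p$pad)
  ymat <- cols %*% W
  ymat <- sweep(ymat, 2, p$b, "+")
  h_out <- (d[1] + 2 * p$pad - p$k) %/% p$stride + 1
  w_out <- (d[2] + 2 * p$pad - p$k) %/% p$stride + 1
  list(y = array(ymat, c(h_out, w_out, p$c_out)), cols = cols, in_dim = d)
}

conv_backward <- function(cache, p, dy, W = p$W) {
  dmat <- matrix(dy, ncol = p$c_out)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dx <- array(cpp_col2im(tcrossprod(dmat, W), cache$in_dim[1], cache$in_dim[2],
                         cache$in_dim[3], p$k, p$stride, p$pad), cache$in_dim)
  list(dW = dW, db = db, dx = dx)
}

# Transposed convolution used when expressing an input-gradient computation
# as a differentiable graph (double backprop for the gradient penalty).
conv_transpose_apply <- function(v, p, out_dim, W = p$W) {
  vmat <- matrix(v, ncol = p$c_out)
  array(cpp_col2im(tcrossprod(vmat, W), out_dim[1], out_dim[2], out_dim[3],
                   p$k, p$stride, p$pad), out_dim)
}

lrelu <- function(z, slope = 0.2) {
  m <- z > 0
  z * m + (slope * z) * (1 - m)
}
lrelu_mask <- function(z, slope = 0.2) {
  m <- z > 0
  m + slope * (1 - m)
}

# --- spectral normalization -------------------------------------------------

# One or more power-iteration steps on the (C_in k^2) x C_out weight matrix;
# u is persistent across calls for warm starts.
spectral_norm <- function(W, u = NULL, n_iter = 2) {
  if (is.null(u)) u <- rnorm(nrow(W))
  for (i in seq_len(n_iter)) {
    v <- as.vector(crossprod(W, u))
    v <- v / max(sqrt(sum(v^2)), 1e-12)
    u <- as.vector(W %*% v)
    u <- u / max(sqrt(sum(u^2)), 1e-12)
  }
  sigma <- as.numeric(crossprod(u, W %*% v))
  list(W_sn = W / sigma, sigma = sigma, u = u, v = v)
}

# Chain rule through W_sn = W / sigma with sigma = u' W v (u, v treated as
# converged singular vectors).
spectral_norm_backward <- function(dW_sn, sn) {
  dW_sn / sn$sigma - (sum(dW_sn * sn$W_sn) / sn$sigma) * tcrossprod(sn$u, sn$v)
}

# --- optimizer --------------------------------------------------------------

rmsprop_init <- function(params) {
  purrr::map(params, function(p) list(W = 0 * p$W, b = 0 * p$b))
}

rmsprop_update <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (i in seq_along(params)) {
    state[[i]]$W <- rho * state[[i]]$W + (1 - rho) * grads[[i]]$dW^2
    state[[i]]$b <- rho * state[[i]]$b + (1 - rho) * grads[[i]]$db^2
    params[[i]]$W <- params[[i]]$W - lr * grads[[i]]$dW / (sqrt(state[[i]]$W) + eps)
    params[[i]]$b <- params[[i]]$b - lr * grads[[i]]$db / (sqrt(state[[i]]$b) + eps)
  }
  list(params = params, state = state)
}

# --- image helpers ----------------------------------------------------------

#' Scale HU intensities to the unit interval and back
#'
#' The harmonizer operates on images linearly rescaled from the clipped HU
#' window to `[0, 1]`.
#'
#' @param x Numeric array of intensities.
#' @param lo,hi HU window bounds.
#' @return Rescaled array.
#' @export
hu_to_unit <- function(x, lo = -45, hi = 125) (pmin(pmax(x, lo), hi) - lo) / (hi - lo)

#' @rdname hu_to_unit
#' @export
unit_to_hu <- function(x, lo = -45, hi = 125) x * (hi - lo) + lo

# Bilinear rotation about the image center; out-of-range samples are 0.
rotate_image <- function(img, angle_deg) {
  if (abs(angle_deg) < 1e-12) return(img)
  th <- angle_deg * pi / 180
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gr <- expand.grid(i = seq_len(H), j = seq_len(W))
  yi <- cos(th) * (gr$i - cy) + sin(th) * (gr$j - cx) + cy
  xj <- -sin(th) * (gr$i - cy) + cos(th) * (gr$j - cx) + cx
  y0 <- floor(yi); x0 <- floor(xj)
  fy <- yi - y0; fx <- xj - x0
  val <- function(r, c) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    out <- numeric(length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  v <- (1 - fy) * (1 - fx) * val(y0, x0) + fy * (1 - fx) * val(y0 + 1, x0) +
    (1 - fy) * fx * val(y0, x0 + 1) + fy * fx * val(y0 + 1, x0 + 1)
  matrix(v, H, W)
}
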