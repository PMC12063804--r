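
#' Generator loss weights
#'
#' Weights of the composite generator objective
#' \deqn{L_{total} = \alpha L_{adv} + \beta L_{perc} + \gamma L_{L1}
#'   + \delta L_{nmse} + \epsilon L_{PSNR}}
#' with defaults (1, 1000, 100, 100, 100) and a gradient-penalty coefficient
#' of 10 for the critic.
#'
#' @param adversarial,perceptual,l1,nmse,psnr Component weights (>= 0).
#' @param gp Gradient-penalty weight for the critic objective.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(adversarial = 1.0, perceptual = 1000, l1 = 100,
                         nmse = 100, psnr = 100, gp = 10.0) {
  w <- list(adversarial = adversarial, perceptual = perceptual, l1 = l1,
            nmse = nmse, psnr = psnr, gp = gp)
  if (any(unlist(w) < 0)) stop("loss weights must be >= 0", call. = FALSE)
  structure(w, class = "loss_weights")
}

#' Training configuration for the image harmonizer
#'
#' @param steps Generator update steps.
#' @param learning_rate Initial RMSprop learning rate for both networks.
#' @param lr_decay Per-step exponential decay factor of the learning rate.
#' @param batch_size Images per update (the paired protocol uses 1).
#' @param test_fraction Held-out fraction of pairs (75/25 split).
#' @param critic_steps Critic updates per generator update.
#' @param dropout Critic dropout rate.
#' @param n_filters Filters per generator texture layer.
#' @param aggregation How the seven texture-layer outputs are merged before
#'   the fusion convolution: `"concat"` (default) or `"sum"`.
#' @param final_kernel Kernel size of the fusion convolution.
#' @param augment Apply random rotation/flip/jitter augmentation.
#' @param aug_max_rotate Max absolute rotation (degrees).
#' @param aug_jitter Max absolute additive intensity jitter.
#' @param backbone Perceptual feature extractor: `"random-conv"` (fixed-seed
#'   random convolutional features, self-contained) or `"identity"` (raw
#'   pixels). The loss contract is backbone-agnostic.
#' @param psnr_norm Normalizer of the (negative) PSNR loss term in dB.
#' @param seed Integer seed for initialization, splits, sampling, dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(steps = 200, learning_rate = 2e-4, lr_decay = 0.999,
                         batch_size = 1L, test_fraction = 0.25,
                         critic_steps = 5L, dropout = 0.25, n_filters = 8L,
                         aggregation = c("concat", "sum"), final_kernel = 3L,
                         augment = TRUE, aug_max_rotate = 15, aug_jitter = 0.05,
                         backbone = "random-conv", psnr_norm = 100, seed = 1L) {
  stopifnot(learning_rate > 0, test_fraction > 0, test_fraction < 1, steps >= 1)
  structure(list(steps = as.integer(steps), learning_rate = learning_rate,
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 test_fraction = test_fraction,
                 critic_steps = as.integer(critic_steps), dropout = dropout,
                 n_filters = as.integer(n_filters),
                 aggregation = match.arg(aggregation),
                 final_kernel = as.integer(final_kernel), augment = augment,
                 aug_max_rotate = aug_max_rotate, aug_jitter = aug_jitter,
                 backbone = backbone, psnr_norm = psnr_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

GEN_KERNELS <- c(15L, 13L, 11L, 9L, 7L, 5L, 3L)
CRITIC_FILTERS <- c(32L, 64L, 128L, 256L)

#' Initialize the shallow multi-receptive-field generator
#'
#' Seven stride-1 ReLU convolutional layers with kernel sizes
#' 15, 13, 11, 9, 7, 5, 3 capture texture at decreasing receptive fields;
#' their outputs are aggregated (concatenation by default) into a final
#' tanh convolution whose output is blended additively with the input and
#' passed through a ramp (clip to `[0, 1]`).
#'
#' @param config A [train_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return A `ct_generator`.
#' @export
generator_init <- function(config = train_config(), seed = config$seed) {
  with_seed(child_seed(seed, "gen"), {
    nf <- config$n_filters
    layers <- vector("list", 7)
    c_in <- 1L
    for (l in 1:7) {
      layers[[l]] <- conv_param(c_in, nf, GEN_KERNELS[l])
      c_in <- nf
    }
    agg_ch <- if (config$aggregation == "concat") 7L * nf else nf
    fusion <- conv_param(agg_ch, 1L, config$final_kernel)
    structure(list(layers = layers, fusion = fusion,
                   aggregation = config$aggregation, n_filters = nf),
              class = "ct_generator")
  })
}

gen_forward <- function(gen, x) {
  d <- c(dim(x), 1L)
  h <- array(x, d)
  caches <- zs <- hs <- vector("list", 7)
  for (l in 1:7) {
    cv <- conv_forward(h, gen$layers[[l]])
    zs[[l]] <- cv$y
    h <- pmax(cv$y, 0)
    hs[[l]] <- h
    caches[[l]] <- cv
  }
  agg <- if (gen$aggregation == "concat") {
    array(unlist(hs, use.names = FALSE), c(d[1], d[2], 7L * gen$n_filters))
  } else {
    Reduce(`+`, hs)
  }
  fus <- conv_forward(agg, gen$fusion)
  f <- tanh(fus$y[, , 1])
  pre <- x + f
  out <- pmin(pmax(pre, 0), 1)
  list(out = out, x = x, f = f, pre = pre, caches = caches, zs = zs,
       fus = fus, agg_dim = dim(agg))
}

gen_backward <- function(gen, cache, dout) {
  ramp_mask <- (cache$pre > 0) & (cache$pre < 1)
  df <- dout * ramp_mask
  du <- array(df * (1 - cache$f^2), c(dim(df), 1L))
  fb <- conv_backward(cache$fus, gen$fusion, du)
  grads <- vector("list", 8)
  grads[[8]] <- list(dW = fb$dW, db = fb$db)
  nf <- gen$n_filters
  dh_next <- NULL   # gradient flowing from layer l+1 back to h_l
  for (l in 7:1) {
    dagg_l <- if (gen$aggregation == "concat") {
      fb$dx[, , ((l - 1) * nf + 1):(l * nf), drop = FALSE]
    } else {
      fb$dx
    }
    dh <- if (is.null(dh_next)) dagg_l else dagg_l + dh_next
    dz <- dh * (cache$zs[[l]] > 0)
    cb <- conv_backward(cache$caches[[l]], gen$layers[[l]], dz)
    grads[[l]] <- list(dW = cb$dW, db = cb$db)
    dh_next <- cb$dx
  }
  grads
}

gen_params <- function(gen) c(gen$layers, list(gen$fusion))
gen_set_params <- function(gen, params) {
  gen$layers <- params[1:7]
  gen$fusion <- params[[8]]
  gen
}

#' Initialize the WGAN critic
#'
#' Four spectrally-normalized stride-2 convolutions with 32, 64, 128, 256
#' filters (kernel 5), LeakyReLU activations and dropout, aggregated by a
#' dense head into a single unbounded scalar score.
#'
#' @param input_shape Image height/width the critic will score.
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @return A `ct_critic`.
#' @export
critic_init <- function(input_shape, config = train_config(), seed = config$seed) {
  critic <- with_seed(child_seed(seed, "critic"), {
    layers <- vector("list", 4)
    c_in <- 1L
    hw <- as.integer(input_shape)
    for (l in 1:4) {
      layers[[l]] <- conv_param(c_in, CRITIC_FILTERS[l], 5L, stride = 2L, pad = 2L)
      layers[[l]]$u <- rnorm(nrow(layers[[l]]$W))
      c_in <- CRITIC_FILTERS[l]
      hw <- (hw + 2L * 2L - 5L) %/% 2L + 1L
    }
    n_flat <- prod(hw) * CRITIC_FILTERS[4]
    head <- list(W = matrix(rnorm(n_flat, sd = sqrt(1 / n_flat)), n_flat, 1),
                 b = 0)
    structure(list(layers = layers, head = head, input_shape = as.integer(input_shape),
                   dropout = config$dropout), class = "ct_critic")
  })
  critic_refresh_sn(critic, n_iter = 30)
}

# Recompute the cached spectrally-normalized weights (after weight updates).
critic_refresh_sn <- function(critic, n_iter = 2) {
  for (l in 1:4) {
    p <- critic$layers[[l]]
    sn <- spectral_norm(p$W, p$u, n_iter = n_iter)
    critic$layers[[l]]$u <- sn$u
    critic$layers[[l]]$sn <- sn
  }
  critic
}

#' Spectrally-normalized critic weights
#'
#' Runs power iteration to convergence and returns each convolutional
#' layer's normalized weight matrix.
#'
#' @param critic A `ct_critic`.
#' @param n_iter Power-iteration steps.
#' @return List of normalized weight matrices.
#' @export
critic_normalized_weights <- function(critic, n_iter = 100) {
  purrr::map(critic$layers, function(p) spectral_norm(p$W, p$u, n_iter)$W_sn)
}

# Forward pass using the cached spectrally-normalized weights; training mode
# applies dropout with masks drawn from `seed`.
critic_forward <- function(critic, x, training = FALSE, seed = NULL) {
  h <- array(x, c(dim(x)[1], dim(x)[2], 1L))
  caches <- vector("list", 4)
  drop_masks <- vector("list", 4)
  for (l in 1:4) {
    p <- critic$layers[[l]]
    sn <- p$sn
    cv <- conv_forward(h, p, W = sn$W_sn)
    z <- cv$y
    h <- lrelu(z)
    if (training && critic$dropout > 0 && !is.null(seed)) {
      m <- with_seed(child_seed(seed, "drop", l),
                     array((runif(length(h)) > critic$dropout) / (1 - critic$dropout),
                           dim(h)))
      drop_masks[[l]] <- m
      h <- h * m
    }
    caches[[l]] <- list(cv = cv, z = z, sn = sn)
  }
  v <- as.vector(h)
  score <- sum(v * critic$head$W) + critic$head$b
  list(score = score, critic = critic,
       cache = list(layers = caches, drop = drop_masks, flat = v,
                    top_dim = dim(h), in_dim = dim(x)))
}

# Backprop dscore through the critic. Layer gradients are returned in the
# spectrally-normalized weight space (chain through the normalization with
# chain_sn_grads, once per combined objective).
critic_backward <- function(critic, cache, dscore = 1) {
  dW_head <- dscore * matrix(cache$flat, ncol = 1)
  db_head <- dscore
  dh <- array(dscore * as.vector(critic$head$W), cache$top_dim)
  grads <- vector("list", 4)
  for (l in 4:1) {
    cl <- cache$layers[[l]]
    if (!is.null(cache$drop[[l]])) dh <- dh * cache$drop[[l]]
    dz <- dh * lrelu_mask(cl$z)
    cb <- conv_backward(cl$cv, critic$layers[[l]], dz, W = cl$sn$W_sn)
    grads[[l]] <- list(dW_sn = cb$dW, db = cb$db)
    dh <- cb$dx
  }
  list(layer_grads = grads, head = list(dW = dW_head, db = db_head),
       dx = dh[, , 1])
}

chain_sn_grads <- function(critic, layer_grads) {
  purrr::map(1:4, function(l) {
    list(dW = spectral_norm_backward(layer_grads[[l]]$dW_sn, critic$layers[[l]]$sn),
         db = layer_grads[[l]]$db)
  })
}

# Gradient of the critic score wrt its input (no dropout), plus the
# activation masks needed for the double-backprop pass.
critic_input_gradient <- function(critic, x) {
  fw <- critic_forward(critic, x, training = FALSE)
  cache <- fw$cache
  G <- array(as.vector(critic$head$W), cache$top_dim)
  vs <- vector("list", 4)    # gated gradients entering each transposed conv
  for (l in 4:1) {
    cl <- cache$layers[[l]]
    M <- lrelu_mask(cl$z)
    v <- G * M
    vs[[l]] <- v
    G <- array(cpp_col2im(tcrossprod(matrix(v, ncol = critic$layers[[l]]$c_out),
                                     cl$sn$W_sn),
                          cl$cv$in_dim[1], cl$cv$in_dim[2], cl$cv$in_dim[3],
                          5L, 2L, 2L), cl$cv$in_dim)
  }
  list(g = G[, , 1], cache = cache, vs = vs, score = fw$score)
}

# Gradient penalty (|grad|_2 - 1)^2 at x_tilde plus its gradient wrt critic
# weights, obtained by differentiating the input-gradient graph with the
# LeakyReLU activation pattern held fixed (exact almost everywhere).
critic_gp_grads <- function(critic, x_tilde) {
  ig <- critic_input_gradient(critic, x_tilde)
  g <- ig$g
  gn <- sqrt(sum(g^2))
  gp <- (gn - 1)^2
  r <- if (gn > 1e-12) 2 * (gn - 1) / gn * g else 0 * g
  S <- array(r, c(dim(g), 1L))
  grads <- vector("list", 4)
  for (l in 1:4) {
    cl <- ig$cache$layers[[l]]
    p <- critic$layers[[l]]
    d <- cl$cv$in_dim
    A <- cpp_im2col(as.numeric(S), d[1], d[2], d[3], p$k, p$stride, p$pad)
    Vmat <- matrix(ig$vs[[l]], ncol = p$c_out)
    grads[[l]] <- list(dW_sn = crossprod(A, Vmat), db = 0 * p$b)
    dV <- A %*% cl$sn$W_sn
    M <- lrelu_mask(cl$z)
    S <- array(dV, dim(cl$z)) * M
  }
  list(gp = gp, layer_grads = grads,
       head = list(dW = matrix(as.vector(S), ncol = 1), db = 0))
}

#' Gradient penalty of a critic on interpolated samples
#'
#' Draws one uniform interpolation coefficient per sample from `seed`, forms
#' the convex combination of real and fake images, and returns the mean of
#' \eqn{(\lVert \nabla_x D(\tilde x) \rVert_2 - 1)^2}, optionally weighted.
#'
#' @param critic A `ct_critic`, or any R function mapping an image matrix to
#'   a scalar score (its input gradient is then obtained by central finite
#'   differences).
#' @param real,fake Image matrices, or 3D arrays of images stacked along the
#'   third dimension; shapes must match.
#' @param seed Integer seed for the interpolation coefficients.
#' @param weight Multiplier (the WGAN-GP objective uses 10).
#' @return Non-negative scalar.
#' @export
gradient_penalty <- function(critic, real, fake, seed, weight = 1.0) {
  if (is.matrix(real)) real <- array(real, c(dim(real), 1L))
  if (is.matrix(fake)) fake <- array(fake, c(dim(fake), 1L))
  if (!identical(dim(real), dim(fake))) {
    stop("shape error: real/fake dimensions differ", call. = FALSE)
  }
  n <- dim(real)[3]
  eps <- with_seed(seed, runif(n))
  pen <- vapply(seq_len(n), function(i) {
    xt <- matrix(eps[i] * real[, , i] + (1 - eps[i]) * fake[, , i],
                 dim(real)[1], dim(real)[2])
    g <- if (inherits(critic, "ct_critic")) {
      critic_input_gradient(critic, xt)$g
    } else {
      numeric_input_gradient(critic, xt)
    }
    (sqrt(sum(g^2)) - 1)^2
  }, numeric(1))
  weight * mean(pen)
}

numeric_input_gradient <- function(f, x, h = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' Composite generator loss
#'
#' Weighted sum of the five generator loss components. Components are logged
#' individually via the `"components"` attribute.
#'
#' @param terms Named numeric vector/list with entries `adversarial`,
#'   `perceptual`, `l1`, `nmse`, `psnr`.
#' @param weights A [loss_weights()].
#' @return Scalar total loss with attribute `"components"`.
#' @export
generator_loss <- function(terms, weights = loss_weights()) {
  terms <- unlist(terms)
  need <- c("adversarial", "perceptual", "l1", "nmse", "psnr")
  miss <- setdiff(need, names(terms))
  if (length(miss)) stop("missing loss component(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- need[!is.finite(terms[need])]
  if (length(bad)) stop("loss error: non-finite component(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  w <- c(weights$adversarial, weights$perceptual, weights$l1, weights$nmse,
         weights$psnr)
  total <- sum(w * terms[need])
  attr(total, "components") <- terms[need]
  total
}

# --- perceptual backbone ----------------------------------------------------

backbone_init <- function(kind, seed) {
  if (kind == "identity") return(structure(list(kind = "identity"), class = "ct_backbone"))
  if (kind != "random-conv") stop("unknown backbone: ", kind, call. = FALSE)
  with_seed(child_seed(seed, "backbone"), {
    structure(list(kind = "random-conv",
                   l1 = conv_param(1L, 8L, 3L),
                   l2 = conv_param(8L, 16L, 3L, stride = 2L, pad = 1L)),
              class = "ct_backbone")
  })
}

backbone_forward <- function(bb, x) {
  if (bb$kind == "identity") {
    return(list(feat = array(x, c(dim(x), 1L)), caches = NULL))
  }
  c1 <- conv_forward(array(x, c(dim(x), 1L)), bb$l1)
  h1 <- pmax(c1$y, 0)
  c2 <- conv_forward(h1, bb$l2)
  h2 <- pmax(c2$y, 0)
  list(feat = h2, caches = list(c1 = c1, c2 = c2, z1 = c1$y, z2 = c2$y))
}

backbone_input_grad <- function(bb, cache, dfeat) {
  if (bb$kind == "identity") return(dfeat[, , 1])
  dz2 <- dfeat * (cache$z2 > 0)
  dh1 <- conv_backward(cache$c2, bb$l2, dz2)$dx
  dz1 <- dh1 * (cache$z1 > 0)
  conv_backward(cache$c1, bb$l1, dz1)$dx[, , 1]
}

# --- training ---------------------------------------------------------------

augment_pair <- function(src, tgt, config, seed) {
  with_seed(seed, {
    ang <- runif(1, -config$aug_max_rotate, config$aug_max_rotate)
    src <- rotate_image(src, ang)
    tgt <- rotate_image(tgt, ang)
    if (runif(1) < 0.5) { src <- src[nrow(src):1, ]; tgt <- tgt[nrow(tgt):1, ] }
    if (runif(1) < 0.5) { src <- src[, ncol(src):1]; tgt <- tgt[, ncol(tgt):1] }
    j <- runif(1, -config$aug_jitter, config$aug_jitter)
    list(src = pmin(pmax(src + j, 0), 1), tgt = pmin(pmax(tgt + j, 0), 1))
  })
}

# Generator loss terms and the gradient of the total loss wrt the output.
generator_terms_and_grad <- function(out, tgt, score_adv, dscore_dout, bb,
                                     weights, psnr_norm) {
  n <- length(out)
  diff <- out - tgt
  mse <- mean(diff^2)
  eps <- 1e-10
  fa <- backbone_forward(bb, out)
  fb <- backbone_forward(bb, tgt)
  fd <- fa$feat - fb$feat
  terms <- c(adversarial = -score_adv,
             perceptual = mean(fd^2),
             l1 = mean(abs(diff)),
             nmse = sum(diff^2) / max(sum(tgt^2), eps),
             psnr = -10 * log10(1 / (mse + eps)) / psnr_norm)
  dadv <- -dscore_dout
  dperc <- backbone_input_grad(bb, fa$caches, 2 * fd / length(fd))
  dl1 <- sign(diff) / n
  dnmse <- 2 * diff / max(sum(tgt^2), eps)
  dpsnr <- (10 / (log(10) * (mse + eps))) / psnr_norm * (2 * diff / n)
  dout <- weights$adversarial * dadv + weights$perceptual * dperc +
    weights$l1 * dl1 + weights$nmse * dnmse + weights$psnr * dpsnr
  list(terms = terms, dout = dout)
}

#' Train a paired image harmonizer (WGAN-GP)
#'
#' Alternates spectrally-normalized critic updates (Wasserstein loss with
#' gradient penalty) with generator updates under the composite loss of
#' [generator_loss()], on spatially aligned (source, target) slice pairs
#' scaled to `[0, 1]`. Fully deterministic for a fixed config seed.
#'
#' @param pairs List of pairs, each a list with matrices `source` and
#'   `target` of identical dimensions, or a list with 3D arrays `source`,
#'   `target` stacked along the third dimension.
#' @param config A [train_config()].
#' @param weights A [loss_weights()].
#' @param source_group,reference_group Optional group tags recorded on the
#'   model.
#' @return A `harmonizer_model` with the trained generator/critic, the full
#'   per-step loss history (tibble) and the train/test split.
#' @export
train_harmonizer <- function(pairs, config = train_config(),
                             weights = loss_weights(),
                             source_group = NA, reference_group = NA) {
  pairs <- normalize_pairs(pairs)
  n_pairs <- length(pairs)
  if (n_pairs < 1) stop("data error: empty pair set", call. = FALSE)
  for (p in pairs) {
    if (!identical(dim(p$source), dim(p$target))) {
      stop("data error: source/target shapes differ", call. = FALSE)
    }
    rng <- range(p$source, p$target)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      stop("scaling error: images must lie in [0, 1]", call. = FALSE)
    }
  }
  hw <- dim(pairs[[1]]$source)
  n_test <- max(if (n_pairs > 1) 1L else 0L, round(config$test_fraction * n_pairs))
  test_idx <- if (n_test > 0) {
    with_seed(child_seed(config$seed, "split"), sample.int(n_pairs, n_test))
  } else integer(0)
  train_idx <- setdiff(seq_len(n_pairs), test_idx)
  if (length(train_idx) == 0) train_idx <- seq_len(n_pairs)

  gen <- generator_init(config)
  critic <- critic_init(hw, config)
  bb <- backbone_init(config$backbone, config$seed)
  g_state <- rmsprop_init(gen_params(gen))
  c_params <- c(critic$layers, list(critic$head))
  c_state <- rmsprop_init(c_params)

  hist <- vector("list", config$steps)
  for (step in seq_len(config$steps)) {
    lr <- config$learning_rate * config$lr_decay^(step - 1)
    step_seed <- child_seed(config$seed, "step", step)

    # -- critic updates (one generated fake per outer step)
    c_loss <- gp_val <- NA_real_
    cs_seed <- child_seed(step_seed, "c")
    i <- with_seed(child_seed(cs_seed, "pick"),
                   train_idx[sample.int(length(train_idx), 1)])
    cpair <- pairs[[i]]
    if (config$augment) {
      a <- augment_pair(cpair$source, cpair$target, config, child_seed(cs_seed, "aug"))
      cpair <- list(source = a$src, target = a$tgt)
    }
    fake <- gen_forward(gen, cpair$source)$out
    for (cs in seq_len(config$critic_steps)) {
      ss <- child_seed(cs_seed, cs)
      pair <- cpair
      fw_f <- critic_forward(critic, fake, training = TRUE, seed = child_seed(ss, "df"))
      fw_r <- critic_forward(critic, pair$target, training = TRUE,
                             seed = child_seed(ss, "dr"))
      bk_f <- critic_backward(critic, fw_f$cache, dscore = 1)
      bk_r <- critic_backward(critic, fw_r$cache, dscore = -1)
      e <- with_seed(child_seed(ss, "eps"), runif(1))
      xt <- e * pair$target + (1 - e) * fake
      gpg <- critic_gp_grads(critic, xt)
      grads <- chain_sn_grads(critic, purrr::map(1:4, function(l) {
        list(dW_sn = bk_f$layer_grads[[l]]$dW_sn + bk_r$layer_grads[[l]]$dW_sn +
               weights$gp * gpg$layer_grads[[l]]$dW_sn,
             db = bk_f$layer_grads[[l]]$db + bk_r$layer_grads[[l]]$db +
               weights$gp * gpg$layer_grads[[l]]$db)
      }))
      grads[[5]] <- list(dW = bk_f$head$dW + bk_r$head$dW + weights$gp * gpg$head$dW,
                         db = bk_f$head$db + bk_r$head$db + weights$gp * gpg$head$db)
      c_params <- c(critic$layers, list(critic$head))
      upd <- rmsprop_update(c_params, grads, c_state, lr)
      c_state <- upd$state
      for (l in 1:4) {
        critic$layers[[l]]$W <- upd$params[[l]]$W
        critic$layers[[l]]$b <- upd$params[[l]]$b
      }
      critic$head$W <- upd$params[[5]]$W
      critic$head$b <- as.numeric(upd$params[[5]]$b)
      critic <- critic_refresh_sn(critic)
      c_loss <- fw_f$score - fw_r$score + weights$gp * gpg$gp
      gp_val <- gpg$gp
    }

    # -- generator update
    ss <- child_seed(step_seed, "g")
    i <- with_seed(child_seed(ss, "pick"),
                   train_idx[sample.int(length(train_idx), 1)])
    pair <- pairs[[i]]
    if (config$augment) {
      a <- augment_pair(pair$source, pair$target, config, child_seed(ss, "aug"))
      pair <- list(source = a$src, target = a$tgt)
    }
    gfw <- gen_forward(gen, pair$source)
    cfw <- critic_forward(critic, gfw$out, training = FALSE)
    cbk <- critic_backward(critic, cfw$cache, dscore = 1)
    tg <- generator_terms_and_grad(gfw$out, pair$target, cfw$score, cbk$dx,
                                   bb, weights, config$psnr_norm)
    total <- generator_loss(as.list(tg$terms), weights)
    if (!is.finite(total) || !is.finite(c_loss)) {
      stop("training diverged (non-finite loss) at step ", step, call. = FALSE)
    }
    ggrads <- gen_backward(gen, gfw, tg$dout)
    gupd <- rmsprop_update(gen_params(gen), ggrads, g_state, lr)
    g_state <- gupd$state
    gen <- gen_set_params(gen, gupd$params)

    hist[[step]] <- tibble(step = step, lr = lr, critic_loss = c_loss,
                           gradient_penalty = gp_val,
                           total = as.numeric(total),
                           adversarial = tg$terms[["adversarial"]],
                           perceptual = tg$terms[["perceptual"]],
                           l1 = tg$terms[["l1"]], nmse = tg$terms[["nmse"]],
                           psnr = tg$terms[["psnr"]])
  }
  structure(list(generator = gen, critic = critic, backbone = bb,
                 weights = weights, config = config,
                 history = dplyr::bind_rows(hist),
                 train_idx = train_idx, test_idx = test_idx,
                 source_group = source_group, reference_group = reference_group),
            class = "harmonizer_model")
}

normalize_pairs <- function(pairs) {
  if (is.list(pairs) && !is.null(pairs$source)) {
    s <- pairs$source; t <- pairs$target
    if (is.matrix(s)) return(list(list(source = s, target = t)))
    return(purrr::map(seq_len(dim(s)[3]),
                      function(i) list(source = s[, , i], target = t[, , i])))
  }
  pairs
}

#' Apply a trained harmonizer to images
#'
#' Runs per-slice generator inference. Inputs must be scaled to `[0, 1]`
#' (see [hu_to_unit()]); outputs have identical shape and stay in `[0, 1]`.
#'
#' @param model A `harmonizer_model` (or a `ct_generator`).
#' @param images Matrix, 3D array (slices along dim 3), or list of matrices.
#' @return Harmonized images of identical shape.
#' @export
harmonize_images <- function(model, images) {
  gen <- if (inherits(model, "harmonizer_model")) model$generator else model
  stopifnot(inherits(gen, "ct_generator"))
  apply_one <- function(img) {
    if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
      stop("scaling error: images must lie in [0, 1]", call. = FALSE)
    }
    gen_forward(gen, img)$out
  }
  if (is.list(images)) return(purrr::map(images, apply_one))
  if (is.matrix(images)) return(apply_one(images))
  if (is.array(images) && length(dim(images)) == 3) {
    out <- images
    for (i in seq_len(dim(images)[3])) out[, , i] <- apply_one(images[, , i])
    return(out)
  }
  stop("unsupported image container", call. = FALSE)
}

#' @export
print.harmonizer_model <- function(x, ...) {
  cat(sprintf("<harmonizer_model> group %s -> %s; %d steps trained; final total loss %.4g\n",
              x$source_group, x$reference_group, nrow(x$history),
              utils::tail(x$history$total, 1)))
  invisible(x)
}

#' Tidy the training history of a harmonizer
#'
#' @param x A `harmonizer_model`.
#' @param ... Unused.
#' @return Long tibble with columns `step`, `component`, `value`.
#' @export
tidy.harmonizer_model <- function(x, ...) {
  tidyr::pivot_longer(x$history, -c("step", "lr"),
                      names_to = "component", values_to = "value")
}

#' One-line training summary of a harmonizer
#'
#' @param x A `harmonizer_model`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.harmonizer_model <- function(x, ...) {
  tibble(steps = nrow(x$history),
         final_total = utils::tail(x$history$total, 1),
         final_nmse = utils::tail(x$history$nmse, 1),
         n_train = length(x$train_idx), n_test = length(x$test_idx))
}

#' Plot harmonizer training curves
#'
#' @param model A `harmonizer_model`.
#' @param components History columns to show.
#' @return A ggplot object.
#' @export
plot_training_history <- function(model, components = c("total", "nmse", "l1")) {
  df <- tidy(model) |> dplyr::filter(.data$component %in% components)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "training step", y = "loss component") +
    ggplot2::theme_minimal()
}
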