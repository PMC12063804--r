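test_that("composite generator loss is the configured weighted sum", {
  terms <- c(adversarial = 1, perceptual = 0.001, l1 = 0.01, nmse = 0.01,
             psnr = 0.01)
  total <- generator_loss(terms)
  expect_equal(as.numeric(total), 5.0)
  expect_equal(attr(total, "components"), terms)

  w <- loss_weights()
  expect_equal(unlist(w[c("adversarial", "perceptual", "l1", "nmse", "psnr")]),
               c(adversarial = 1.0, perceptual = 1000, l1 = 100, nmse = 100,
                 psnr = 100))
  expect_equal(w$gp, 10.0)

  zero <- generator_loss(c(adversarial = 0, perceptual = 0, l1 = 0,
                           nmse = 0, psnr = 0))
  expect_equal(as.numeric(zero), 0)
  expect_error(generator_loss(c(adversarial = NaN, perceptual = 0, l1 = 0,
                                nmse = 0, psnr = 0)), "adversarial")
  expect_error(generator_loss(c(adversarial = 0, l1 = 0, nmse = 0, psnr = 0)),
               "perceptual")
})

test_that("gradient penalty matches analytic values for linear critics", {
  r <- matrix(0.3, 1, 1)
  f <- matrix(0.7, 1, 1)
  unit <- function(img) sum(img)
  expect_lt(gradient_penalty(unit, r, f, seed = 1), 1e-10)
  twice <- function(img) 2 * sum(img)
  expect_equal(gradient_penalty(twice, r, f, seed = 1), 1, tolerance = 1e-6)
  expect_equal(gradient_penalty(twice, r, f, seed = 1, weight = 10), 10,
               tolerance = 1e-6)
  # scaling a linear critic by c scales the penalty as (c - 1)^2
  for (cc in c(0.5, 1, 2)) {
    lin <- function(img) cc * sum(img)
    expect_equal(gradient_penalty(lin, r, f, seed = 3), (cc - 1)^2,
                 tolerance = 1e-6)
  }
  # a real critic yields a non-negative penalty, on batches too
  critic <- critic_init(c(16, 16), train_config(seed = 4))
  batch <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_gte(gradient_penalty(critic, batch, 1 - batch, seed = 5), 0)
  expect_error(gradient_penalty(critic, batch, batch[, 1:8, ], seed = 1),
               "shape error")
})

test_that("generator preserves spatial dimensions and the output range", {
  cfg <- train_config(n_filters = 2, seed = 8)
  gen <- generator_init(cfg)
  for (d in list(c(15, 15), c(17, 20), c(32, 32))) {
    x <- matrix(runif(prod(d)), d[1], d[2])
    out <- harmonize_images(gen, x)
    expect_identical(dim(out), dim(x))
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }
  x <- matrix(runif(16 * 16), 16, 16)
  expect_identical(harmonize_images(gen, x), harmonize_images(gen, x))
  expect_error(harmonize_images(gen, x + 5), "scaling error")
})

test_that("a zeroed fusion layer reduces the generator to the identity ramp", {
  cfg <- train_config(n_filters = 2, seed = 9)
  gen <- generator_init(cfg)
  gen$fusion$W[] <- 0
  gen$fusion$b[] <- 0
  x <- matrix(runif(18 * 18), 18, 18)
  expect_equal(harmonize_images(gen, x), x, tolerance = 1e-12)
})

test_that("critic weights satisfy the spectral-norm constraint and score a scalar", {
  critic <- critic_init(c(16, 16), train_config(seed = 10))
  for (W in critic_normalized_weights(critic, n_iter = 200)) {
    expect_lte(svd(W, nu = 0, nv = 0)$d[1], 1 + 1e-3)
  }
  s <- ctharmony:::critic_forward(critic, matrix(runif(256), 16, 16))$score
  expect_length(s, 1)
  expect_true(is.finite(s))
})

test_that("short training runs stay finite, log a consistent decomposition, and split 75/25", {
  pairs <- make_slices(8, size = 16)
  pairs <- lapply(pairs, function(m) list(source = m, target = m))
  cfg <- train_config(steps = 8, n_filters = 2, seed = 11)
  model <- train_harmonizer(pairs, cfg)
  h <- model$history
  expect_equal(nrow(h), 8)
  expect_true(all(is.finite(as.matrix(h))))
  recomposed <- with(h, 1 * adversarial + 1000 * perceptual + 100 * l1 +
                       100 * nmse + 100 * psnr)
  expect_lt(max(abs(h$total - recomposed)), 1e-6)
  expect_equal(length(model$test_idx), 2)
  expect_equal(sort(c(model$train_idx, model$test_idx)), 1:8)
  # learning-rate schedule decays exponentially from the configured rate
  expect_equal(h$lr[1], 2e-4)
  expect_equal(h$lr, 2e-4 * cfg$lr_decay^(h$step - 1))

  expect_error(train_harmonizer(list(), cfg), "data error")
  bad <- list(list(source = matrix(2, 4, 4), target = matrix(0.5, 4, 4)))
  expect_error(train_harmonizer(bad, cfg), "scaling error")
})

test_that("training configuration defaults match the paired protocol", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 2e-4)
  expect_equal(cfg$batch_size, 1L)
  expect_equal(cfg$test_fraction, 0.25)
  expect_equal(cfg$critic_steps, 5L)
})

test_that("tidy/glance expose the training history", {
  pairs <- lapply(make_slices(4, size = 16), function(m) list(source = m, target = m))
  model <- train_harmonizer(pairs, train_config(steps = 3, n_filters = 2, seed = 12))
  td <- tidy(model)
  expect_true(all(c("step", "component", "value") %in% names(td)))
  expect_true("nmse" %in% td$component)
  g <- glance(model)
  expect_equal(g$steps, 3)
  expect_true(is.finite(g$final_nmse))
})
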