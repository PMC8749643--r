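test_that("architecture arithmetic and build errors follow the layer stack", {
  cfg <- cnn_config(epochs = 10)
  m6 <- suppressWarnings(build_cnn(cfg, input_length = 6))
  # 6 -> 3 -> 1 after the two pool layers: first dense sees 1 * filters_block2
  expect_equal(nrow(m6$params$dense1_W), 1 * cfg$filters_block2)
  m12 <- suppressWarnings(build_cnn(cfg, input_length = 12))
  expect_equal(nrow(m12$params$dense1_W), 3 * cfg$filters_block2)
  expect_error(build_cnn(cfg, input_length = 3), "n_blocks = 1")
  m3 <- suppressWarnings(build_cnn(cfg, input_length = 3, n_blocks = 1))
  expect_equal(nrow(m3$params$dense1_W), 1 * cfg$filters_block1)
  # kernels wider than a layer's input are clamped with a warning
  expect_warning(build_cnn(cnn_config(kernel_size = 32, epochs = 10),
                           input_length = 6),
                 class = "oxispec_kernel_clamp")
})

test_that("softmax outputs are proper seeded-deterministic weights", {
  cfg <- cnn_config(epochs = 10, seed = 7)
  m1 <- suppressWarnings(build_cnn(cfg, input_length = 6))
  m2 <- suppressWarnings(build_cnn(cfg, input_length = 6))
  x <- matrix(seq(0, 1, length.out = 18), 3, 6)
  w1 <- predict(m1, x, type = "weights")
  expect_identical(w1, predict(m2, x, type = "weights"))
  expect_true(all(w1 >= 0))
  expect_equal(rowSums(w1), rep(1, 3), tolerance = 1e-6)
  expect_equal(dim(w1), c(3, 10))
  expect_error(predict(m1, matrix(0, 2, 5)), "expects")
})

test_that("backpropagated gradients match numerical differentiation", {
  cfg <- suppressWarnings(cnn_config(filters_block1 = 3, filters_block2 = 4,
                                     n_dense_layers = 1, kernel_size = 3,
                                     dropout_ratio = 0.01, dense_nodes = 5,
                                     epochs = 10, seed = 2))
  m <- build_cnn(cfg, input_length = 6)
  set.seed(3)
  # random non-zero parameters keep activations away from the exact ReLU
  # kink (zero biases put all-zero receptive fields precisely on it, where
  # the subgradient and a central difference legitimately disagree)
  m$params <- lapply(m$params, function(p) {
    p[] <- rnorm(length(p), 0, 0.3)
    p
  })
  X <- array(runif(4 * 6), c(4, 6, 1))
  Y <- diag(10)[sample(1:10, 4), ]
  loss_at <- function(params) {
    out <- net_forward(m$layers, params, X, training = FALSE)
    softmax_ce(out$logits, Y)$loss
  }
  fwd <- net_forward(m$layers, m$params, X, training = FALSE)
  sc <- softmax_ce(fwd$logits, Y)
  grads <- net_backward(m$layers, m$params, fwd$caches, sc$dZ)
  h <- 1e-5
  for (nm in c("conv1_W", "conv3_b", "dense1_W", "out_b")) {
    p <- m$params
    idx <- sample(length(p[[nm]]), min(5, length(p[[nm]])))
    for (j in idx) {
      p[[nm]][j] <- m$params[[nm]][j] + h
      up <- loss_at(p)
      p[[nm]][j] <- m$params[[nm]][j] - h
      dn <- loss_at(p)
      p[[nm]][j] <- m$params[[nm]][j]
      expect_equal(grads[[nm]][j], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is reproducible under the seed", {
  fit <- small_model()
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  fit2 <- oxi_cnn(small_dataset(), config = cnn_config(epochs = 60, seed = 1))
  expect_equal(fit$history$loss, fit2$history$loss, tolerance = 1e-12)
  expect_identical(predict(fit, small_dataset()$X[1:5, ]),
                   predict(fit2, small_dataset()$X[1:5, ]))
  # converged model recovers its training exemplars
  expect_gt(mean(predict(fit, small_dataset(), type = "class") ==
                   small_dataset()$y), 0.9)
})

test_that("a single-class degenerate dataset is learned trivially", {
  ds <- small_dataset()
  keep <- ds$y == 91
  fit <- suppressWarnings(oxi_cnn(ds$X[keep, ], ds$y[keep],
                                  config = cnn_config(epochs = 15, seed = 1),
                                  label_vector = 91))
  expect_equal(unname(fit$history$accuracy[15]), 1)
  expect_lt(fit$history$loss[15], 0.05)
})

test_that("expectation decoding reproduces its closed-form examples", {
  labels <- seq(81, 99, by = 2)
  one_hot_99 <- c(rep(0, 9), 1)
  expect_equal(decode_spo2(one_hot_99, labels), 99)
  even_split <- c(rep(0, 8), 0.5, 0.5)
  expect_equal(decode_spo2(even_split, labels), 98)
  expect_equal(decode_spo2(rep(0.1, 10), labels), 90)
  expect_error(decode_spo2(c(0.5, 0.6), c(81, 83)), "sum to 1")
  expect_error(decode_spo2(rep(0.1, 10), c(81, 83)), "lengths differ")
})

test_that("decoding is monotone in mass shifts and stays within the label range", {
  labels <- seq(81, 99, by = 2)
  set.seed(5)
  for (i in 1:50) {
    w <- runif(10)
    w <- w / sum(w)
    d <- decode_spo2(w, labels)
    expect_gte(d, 81)
    expect_lte(d, 99)
    # moving mass from a lower to a higher label strictly increases it
    lo <- which(w > 0.05)[1]
    hi <- 10
    if (lo < hi) {
      w2 <- w
      w2[lo] <- w2[lo] - 0.05
      w2[hi] <- w2[hi] + 0.05
      expect_gt(decode_spo2(w2, labels), d)
    }
  }
  # argmax and expectation agree on one-hot outputs
  for (k in 1:10) {
    w <- numeric(10); w[k] <- 1
    expect_equal(decode_spo2(w, labels), labels[k])
  }
})

test_that("dropout is train-only: inference is deterministic and methods work", {
  fit <- small_model()
  x <- small_dataset()$X[1:4, ]
  expect_identical(predict(fit, x), predict(fit, x))
  expect_equal(length(residuals(fit)), nrow(small_dataset()$X))
  expect_equal(fitted(fit), predict(fit, small_dataset()$X, type = "spo2"))
  expect_output(print(fit), "1D-CNN")
  expect_output(summary(fit), "parameters")
  expect_type(coef(fit), "list")
})

test_that("out-of-bounds configurations warn but extreme learning rates abort cleanly", {
  expect_warning(cnn_config(epochs = 5), class = "oxispec_config_bounds")
  expect_warning(cnn_config(filters_block1 = 128),
                 class = "oxispec_config_bounds")
  expect_silent(cnn_config(epochs = 30))
})
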