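test_that("default spaces reproduce the published searching conditions", {
  g <- search_space_grid()
  expect_equal(g$filters_block1, c(2, 4, 8, 16, 32, 64))
  expect_equal(g$dropout_ratio, seq(0.1, 1, by = 0.1))
  expect_equal(g$learning_rate, c(1e-4, 1e-3, 1e-2, 1e-1))
  b <- search_space_bounds()
  expect_equal(c(b$kernel_size$low, b$kernel_size$high), c(2, 32))
  expect_equal(b$learning_rate$type, "log-real")
  expect_equal(c(b$epochs$low, b$epochs$high), c(10, 500))
  expect_error(search_space_grid(epochs = numeric(0)), "non-empty")
  expect_error(search_space_bounds(epochs = c(50, 20)), "low < high")
})

test_that("the full grid is refused and small grids are searched exhaustively", {
  ds <- small_dataset()
  expect_error(grid_search(search_space_grid(), ds), "pin axes")
  # single point: returned as best with a refit model
  single <- search_space_grid(
    filters_block1 = 4, filters_block2 = 4, n_dense_layers = 2,
    kernel_size = 3, dropout_ratio = 0.1, dense_nodes = 10,
    learning_rate = 1e-3, batch_size = 50, epochs = 10)
  res <- grid_search(single, ds, k_folds = 2, seed = 1)
  expect_equal(nrow(res$trials), 1)
  expect_equal(res$best_score, res$trials$mean_score[1])
  expect_s3_class(res$model, "oxi_cnn")
  expect_true(res$model$fitted)
})

test_that("grid search prefers the properly trained of two candidate configs", {
  ds <- small_dataset()
  two <- search_space_grid(
    filters_block1 = 8, filters_block2 = 8, n_dense_layers = 2,
    kernel_size = 3, dropout_ratio = 0.1, dense_nodes = 20,
    learning_rate = 1e-3, batch_size = 50, epochs = c(1, 30))
  res <- grid_search(two, ds, k_folds = 2, seed = 1)
  expect_equal(nrow(res$trials), 2)
  expect_equal(res$best_config$epochs, 30)
  expect_equal(res$best_score, max(res$trials$mean_score))
  expect_equal(res$trials$mean_score,
               rowMeans(res$trials[, c("fold1", "fold2")]))
})

test_that("Bayesian optimization solves a 1-D objective to the brute-force top decile", {
  # smooth objective of the learning rate alone, optimum at 10^-2.5
  f <- function(v) -(log10(v$learning_rate) + 2.5)^2
  res <- bayes_opt(search_space_bounds(), objective = f,
                   n_trials = 25, seed = 4)
  grid <- exp(seq(log(1e-4), log(0.1), length.out = 1000))
  brute <- -(log10(grid) + 2.5)^2
  expect_gte(res$best_score, unname(quantile(brute, 0.9)))
  # every proposal respects the box
  b <- search_space_bounds()
  for (nm in names(b)) {
    expect_true(all(res$trials[[nm]] >= b[[nm]]$low - 1e-9))
    expect_true(all(res$trials[[nm]] <= b[[nm]]$high + 1e-9))
    if (b[[nm]]$type == "integer") {
      expect_true(all(res$trials[[nm]] == round(res$trials[[nm]])))
    }
  }
  # different seeds explore differently but stay in bounds
  res2 <- bayes_opt(search_space_bounds(), objective = f,
                    n_trials = 25, seed = 5)
  expect_false(identical(res$trials$learning_rate, res2$trials$learning_rate))
  # same seed reproduces the trial sequence exactly
  res3 <- bayes_opt(search_space_bounds(), objective = f,
                    n_trials = 25, seed = 4)
  expect_equal(res$trials$mean_score, res3$trials$mean_score)
})

test_that("coarse-then-fine refinement shrinks the box and never degrades the best", {
  f <- function(v) -(log10(v$learning_rate) + 2.5)^2 -
    0.1 * (v$dropout_ratio - 0.3)^2
  res <- coarse_then_fine(search_space_bounds(), stage2_shrink = 0.25,
                          n_trials = 10, seed = 2, objective = f)
  b1 <- search_space_bounds()
  for (nm in names(b1)) {
    expect_gte(res$stage2_space[[nm]]$low, b1[[nm]]$low)
    expect_lte(res$stage2_space[[nm]]$high, b1[[nm]]$high)
  }
  s1_best <- max(res$trials$mean_score[res$trials$stage == 1])
  expect_gte(res$best_score, s1_best)
  expect_equal(res$best_score, max(res$trials$mean_score))
})
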