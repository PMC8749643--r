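test_that("accuracy counts argmax agreement, including hand-checked fixtures", {
  fit <- small_model()
  ds <- small_dataset()
  # perfect and chance-level sanity anchors via label permutations
  pred <- predict(fit, ds$X, type = "class")
  expect_equal(accuracy(fit, ds$X, y = pred), 1)
  expect_equal(accuracy(fit, ds$X, y = rep(-1, nrow(ds$X))), 0)
  # 5-row fixture against a manual count
  x5 <- ds$X[1:5, ]
  p5 <- predict(fit, x5, type = "class")
  y5 <- c(p5[1], p5[2], -1, p5[4], -1)  # 3 of 5 correct by construction
  expect_equal(accuracy(fit, x5, y = y5), 3 / 5)
  expect_error(accuracy(fit, ds$X[0, , drop = FALSE], y = numeric(0)),
               "non-empty")
})

test_that("deviation reports aggregate absolute errors per concentration", {
  # exact prediction: all zeros
  r0 <- deviation_report(c(81, 91, 99), c(81, 91, 99))
  expect_true(all(r0$per_label$max_abs_deviation == 0))
  expect_equal(r0$total_relative_error, 0)
  # hand-computed two-point example
  r <- deviation_report(c(89, 91), c(90, 90))
  expect_equal(r$per_label$label, 90)
  expect_equal(r$per_label$max_abs_deviation, 1)
  expect_equal(r$per_label$mean_abs_deviation, 1)
  expect_equal(r$per_label$std_deviation, 0)
  expect_equal(r$total_relative_error, 1 / 90 * 100, tolerance = 1e-12)
  # max >= mean >= 0 on random inputs, both std conventions
  set.seed(8)
  truth <- sample(seq(81, 99, 2), 200, replace = TRUE)
  decoded <- truth + rnorm(200)
  for (std in c("population", "sample")) {
    rep <- deviation_report(decoded, truth, std = std)
    expect_true(all(rep$per_label$max_abs_deviation >=
                      rep$per_label$mean_abs_deviation))
    expect_true(all(rep$per_label$mean_abs_deviation >= 0))
  }
  expect_error(deviation_report(1:3, 1:2), "equal length")
})

test_that("calibration fits recover affine relations and match brute-force R^2", {
  ref <- c(81, 83, 85, 87, 89, 91, 93, 95, 97, 99)
  f1 <- calibration_fit(ref, ref)
  expect_equal(f1$slope, 1, tolerance = 1e-12)
  expect_equal(f1$intercept, 0, tolerance = 1e-9)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  f2 <- calibration_fit(2 * ref + 3, ref)
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 3, tolerance = 1e-9)
  # noisy 10-point fixture, R^2 against the explicit 1 - SSres/SStot
  pred <- c(81.4, 82.6, 85.3, 86.8, 89.4, 91.2, 92.6, 95.5, 96.8, 98.9)
  f3 <- calibration_fit(pred, ref)
  beta <- cov(ref, pred) / var(ref)
  alpha <- mean(pred) - beta * mean(ref)
  ss_res <- sum((pred - alpha - beta * ref)^2)
  ss_tot <- sum((pred - mean(pred))^2)
  expect_equal(f3$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_error(calibration_fit(1:5, rep(90, 5)), "degenerate")
  expect_error(calibration_fit(1:2, 1:2), "at least 3")
})

test_that("the ablation grid is complete, seeded and reproduces the region ranking", {
  frames <- clean_frames()
  rep1 <- run_ablation(frames, regions = c("FIRST", "SECOND"),
                       noise_ratios = c(0.02, 0.05),
                       config = cnn_config(epochs = 20, seed = 1),
                       n_rows_per_label = 40, base_seed = 11)
  g <- rep1$grid
  expect_equal(nrow(g), 4)
  expect_true(all(is.na(g$error)))
  expect_true(all(g$accuracy_class >= 0 & g$accuracy_class <= 1))
  for (r in unique(g$noise_ratio)) {
    expect_gte(g$accuracy_class[g$region == "SECOND" & g$noise_ratio == r],
               g$accuracy_class[g$region == "FIRST" & g$noise_ratio == r])
  }
  # cell-by-cell reproducibility under the derived seeds
  rep2 <- run_ablation(frames, regions = c("FIRST", "SECOND"),
                       noise_ratios = c(0.02, 0.05),
                       config = cnn_config(epochs = 20, seed = 1),
                       n_rows_per_label = 40, base_seed = 11)
  expect_equal(rep1$grid$accuracy_class, rep2$grid$accuracy_class)
  # three-channel sub-regions run with the single-block fallback
  rep3 <- run_ablation(frames, regions = "S24", noise_ratios = 0.02,
                       config = cnn_config(epochs = 15, seed = 1),
                       n_rows_per_label = 30, base_seed = 3)
  expect_true(is.na(rep3$grid$error[1]))
})

test_that("decoded accuracy at the +/-1% band dominates argmax accuracy", {
  fit <- small_model()
  ds <- small_dataset()
  expect_gte(accuracy(fit, ds, type = "decoded", tolerance = 1),
             accuracy(fit, ds, type = "class"))
})
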