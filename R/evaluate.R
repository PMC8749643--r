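#' Stratified train/test split of a labeled dataset
#'
#' @param dataset A `labeled_dataset`.
#' @param prop Training proportion (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` `labeled_dataset`s.
#' @export
train_test_split <- function(dataset, prop = 0.8, seed = 1) {
  if (prop <= 0 || prop >= 1) stop("prop must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  take <- logical(nrow(dataset$X))
  for (cl in unique(dataset$y)) {
    idx <- sample(which(dataset$y == cl))
    take[idx[seq_len(round(prop * length(idx)))]] <- TRUE
  }
  subset_ds <- function(keep) {
    d <- dataset
    d$X <- dataset$X[keep, , drop = FALSE]
    d$y <- dataset$y[keep]
    d
  }
  list(train = subset_ds(take), test = subset_ds(!take))
}

#' Test-set accuracy of a fitted classifier
#'
#' `type = "class"` (default) is argmax classification accuracy: the
#' fraction of rows whose highest-weight class equals the true label.
#' `type = "decoded"` instead counts a row as correct when the
#' expectation-decoded SpO2 lies within `tolerance` percentage points of
#' the true label; both notions are reported throughout the ablation
#' study because either reading of "accuracy" is defensible.
#'
#' @param model A fitted `oxi_cnn`.
#' @param test A `labeled_dataset` (or matrix) with true labels `y`.
#' @param y True labels when `test` is a matrix.
#' @param type `"class"` or `"decoded"`.
#' @param tolerance Half-width of the correctness band for decoded
#'   accuracy, in SpO2 percentage points.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(model, test, y = NULL, type = c("class", "decoded"),
                     tolerance = 1) {
  type <- match.arg(type)
  if (inherits(test, "labeled_dataset")) {
    y <- test$y
    test <- test$X
  }
  if (is.null(y) || nrow(test) == 0) {
    stop("test set must be non-empty and labeled", call. = FALSE)
  }
  if (type == "class") {
    mean(predict(model, test, type = "class") == y)
  } else {
    mean(abs(predict(model, test, type = "spo2") - y) <= tolerance)
  }
}

#' Per-concentration deviation report
#'
#' For each label: the maximum, mean and standard deviation of the
#' absolute deviation between the expectation-decoded SpO2 and the true
#' label; plus the total relative error, defined as the mean over all
#' rows of |decoded - truth| / truth, in percent.
#'
#' @param decoded Per-row decoded SpO2 values.
#' @param truth Per-row true labels.
#' @param std `"population"` (divide by n, default) or `"sample"`
#'   (divide by n-1).
#' @return Object of class `deviation_report`: data.frame `per_label`
#'   with columns `label`, `max_abs_deviation`, `mean_abs_deviation`,
#'   `std_deviation`, and scalar `total_relative_error` (percent).
#' @export
#' @examples
#' deviation_report(c(89, 91), c(90, 90))
deviation_report <- function(decoded, truth,
                             std = c("population", "sample")) {
  std <- match.arg(std)
  if (length(decoded) != length(truth)) {
    stop("decoded and truth must have equal length", call. = FALSE)
  }
  dev <- abs(decoded - truth)
  labels <- sort(unique(truth))
  per_label <- do.call(rbind, lapply(labels, function(l) {
    d <- dev[truth == l]
    v <- mean((d - mean(d))^2)
    if (std == "sample") v <- v * length(d) / max(1, length(d) - 1)
    data.frame(label = l,
               max_abs_deviation = max(d),
               mean_abs_deviation = mean(d),
               std_deviation = sqrt(v))
  }))
  structure(list(
    per_label = per_label,
    total_relative_error = mean(dev / truth) * 100,
    std = std
  ), class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("Per-concentration deviation of decoded SpO2 (%):\n")
  print(x$per_label, row.names = FALSE, digits = 3)
  cat(sprintf("Total relative error: %.3f%%\n", x$total_relative_error))
  invisible(x)
}

#' Calibration line of predicted versus reference SpO2
#'
#' Ordinary least squares fit of `predicted ~ reference` with its
#' coefficient of determination; a well calibrated measurement has slope
#' close to 1, intercept close to 0 and R^2 close to 1.
#'
#' @param predicted Predicted SpO2 values (at least 3).
#' @param reference Reference readings (non-constant).
#' @return Object of class `calibration_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
#' @examples
#' calibration_fit(c(81, 85.2, 88.9, 93, 97.1), c(81, 85, 89, 93, 97))
calibration_fit <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) < 3) {
    stop("need at least 3 paired points", call. = FALSE)
  }
  if (stats::var(reference) == 0) {
    stop("degenerate fit: reference values are constant", call. = FALSE)
  }
  fit <- stats::lm(predicted ~ reference)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
    n = length(predicted)
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> predicted = %.4f * reference %+.4f  (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Region-by-noise ablation study
#'
#' For every combination of spectral region and augmentation noise
#' ratio: build the dataset from the given frames, optionally tune the
#' configuration with a small budgeted search, train, and measure
#' test-set accuracy on a stratified hold-out split. Per-cell seeds are
#' derived deterministically from `base_seed` and the cell index;
#' per-cell failures are recorded and the grid continues. Sub-regions
#' with fewer than 4 channels are trained with a single conv-pool block.
#'
#' @param frames Labeled frames, one per concentration (see
#'   [generate_sweep()]).
#' @param regions Character vector of region preset names.
#' @param noise_ratios Noise ratios (default the studied 0, 1, 2, 5,
#'   10 percent).
#' @param config Base [cnn_config()].
#' @param optimizer `"none"` (train `config` as given), `"grid"` or
#'   `"bayes"` (tune with a small budget first).
#' @param budget Number of search trials (or grid points) when tuning.
#' @param n_rows_per_label Dataset rows per concentration.
#' @param split Training proportion of the stratified split.
#' @param base_seed Integer seed from which all per-cell seeds derive.
#' @return Object of class `ablation_report`: data.frame `grid` with
#'   columns `region`, `noise_ratio`, `optimizer`, `accuracy_class`,
#'   `accuracy_decoded`, `seed`, `error` (NA on success).
#' @export
run_ablation <- function(frames, regions = c("FIRST", "SECOND", "FULL"),
                         noise_ratios = c(0, 0.01, 0.02, 0.05, 0.10),
                         config = cnn_config(),
                         optimizer = c("none", "grid", "bayes"),
                         budget = 5, n_rows_per_label = 200,
                         split = 0.8, base_seed = 1) {
  optimizer <- match.arg(optimizer)
  cells <- expand.grid(region = regions, noise_ratio = noise_ratios,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell_seed <- (base_seed + 7919L * i) %% .Machine$integer.max
    region <- cells$region[i]
    r <- cells$noise_ratio[i]
    rows[[i]] <- tryCatch({
      ds <- suppressWarnings(build_dataset(frames, region, noise_ratio = r,
                                           n_rows_per_label = n_rows_per_label,
                                           seed = cell_seed))
      sp <- train_test_split(ds, prop = split, seed = cell_seed)
      cfg <- config
      if (optimizer == "grid") {
        gs <- search_space_grid(
          learning_rate = c(1e-4, 1e-3, 1e-2),
          filters_block1 = config$filters_block1,
          filters_block2 = config$filters_block2,
          n_dense_layers = config$n_dense_layers,
          kernel_size = config$kernel_size,
          dropout_ratio = config$dropout_ratio,
          dense_nodes = config$dense_nodes,
          batch_size = config$batch_size,
          epochs = config$epochs)
        cfg <- grid_search(gs, sp$train, k_folds = 2,
                           seed = cell_seed)$best_config
      } else if (optimizer == "bayes") {
        bo <- bayes_opt(search_space_bounds(), sp$train,
                        n_trials = max(5, budget), k_folds = 2,
                        seed = cell_seed)
        cfg <- bo$best_config
      }
      n_blocks <- if (length(region_spec(region)$centers_nm) < 4) 1 else 2
      fit <- suppressWarnings(oxi_cnn(sp$train, config = cfg,
                                      n_blocks = n_blocks))
      data.frame(region = region, noise_ratio = r, optimizer = optimizer,
                 accuracy_class = accuracy(fit, sp$test, type = "class"),
                 accuracy_decoded = accuracy(fit, sp$test, type = "decoded"),
                 seed = cell_seed, error = NA_character_)
    }, error = function(e) {
      data.frame(region = region, noise_ratio = r, optimizer = optimizer,
                 accuracy_class = NA_real_, accuracy_decoded = NA_real_,
                 seed = cell_seed, error = conditionMessage(e))
    })
  }
  structure(list(grid = do.call(rbind, rows)), class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Region x noise ablation (test accuracy):\n")
  print(x$grid, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Bar chart of an ablation report
#'
#' @param x An `ablation_report`.
#' @param type Accuracy column to plot.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.ablation_report <- function(x, type = c("class", "decoded"), ...) {
  type <- match.arg(type)
  col <- paste0("accuracy_", type)
  tab <- stats::xtabs(x$grid[[col]] ~ x$grid$region + x$grid$noise_ratio)
  graphics::barplot(tab, beside = TRUE, legend.text = rownames(tab),
                    xlab = "noise ratio", ylab = paste(type, "accuracy"),
                    ylim = c(0, 1), ...)
  invisible(x)
}
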