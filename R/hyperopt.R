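#' Hyperparameter search spaces
#'
#' `search_space_grid()` returns the exhaustive value lists of the grid
#' search study; `search_space_bounds()` the continuous/integer box of
#' the Bayesian optimization study (learning rate searched on a log
#' scale). Both reproduce the published searching conditions exactly and
#' can be subset or overridden per axis.
#'
#' @param ... Named overrides: for the grid, a vector of values per
#'   axis; for the bounds, a `c(low, high)` pair per axis.
#' @return For the grid: named list of value vectors, class
#'   `search_space_grid`. For the bounds: named list with elements
#'   `low`, `high`, `type` (`"integer"`, `"real"` or `"log-real"`),
#'   class `search_space_bounds`.
#' @export
#' @examples
#' search_space_grid(epochs = 30)$kernel_size
search_space_grid <- function(...) {
  space <- list(
    filters_block1 = c(2, 4, 8, 16, 32, 64),
    filters_block2 = c(2, 4, 8, 16, 32, 64),
    n_dense_layers = c(2, 4, 6, 8, 10),
    kernel_size    = c(2, 4, 8, 16, 32),
    dropout_ratio  = seq(0.1, 1, by = 0.1),
    dense_nodes    = seq(10, 100, by = 10),
    learning_rate  = c(1e-4, 1e-3, 1e-2, 1e-1),
    batch_size     = c(10, 50, 100, 200, 300),
    epochs         = c(10, 50, 100, 200, 300, 400, 500)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(space))
  if (length(bad)) stop("unknown axes: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(vapply(over, length, integer(1)) == 0)) {
    stop("axis value lists must be non-empty", call. = FALSE)
  }
  space[names(over)] <- over
  structure(space, class = "search_space_grid")
}

#' @rdname search_space_grid
#' @export
search_space_bounds <- function(...) {
  mk <- function(lo, hi, type) list(low = lo, high = hi, type = type)
  space <- list(
    filters_block1 = mk(2, 64, "integer"),
    filters_block2 = mk(2, 64, "integer"),
    n_dense_layers = mk(1, 10, "integer"),
    kernel_size    = mk(2, 32, "integer"),
    dropout_ratio  = mk(0.01, 1, "real"),
    dense_nodes    = mk(1, 100, "integer"),
    learning_rate  = mk(1e-4, 0.1, "log-real"),
    batch_size     = mk(10, 300, "integer"),
    epochs         = mk(10, 500, "integer")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(space))
  if (length(bad)) stop("unknown axes: ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(over)) {
    v <- over[[nm]]
    if (length(v) != 2 || v[1] >= v[2]) {
      stop("bounds for ", nm, " must be c(low, high) with low < high",
           call. = FALSE)
    }
    space[[nm]]$low <- v[1]; space[[nm]]$high <- v[2]
  }
  structure(space, class = "search_space_bounds")
}

# Stratified k-fold assignment: per class, shuffled then dealt cyclically.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# k-fold CV argmax accuracy of one config on a labeled dataset.
cv_score <- function(config, dataset, k_folds, fold) {
  scores <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    test <- fold == f
    fit <- suppressWarnings(oxi_cnn(dataset$X[!test, , drop = FALSE],
                                    dataset$y[!test], config = config,
                                    label_vector = dataset$label_vector))
    scores[f] <- mean(predict(fit, dataset$X[test, , drop = FALSE],
                              type = "class") == dataset$y[test])
  }
  scores
}

config_from_values <- function(values) {
  suppressWarnings(do.call(cnn_config, as.list(values)))
}

#' Exhaustive grid search with stratified cross-validation
#'
#' Evaluates every point of a list-mode search space by stratified
#' k-fold cross-validated argmax accuracy, then refits the best
#' configuration on the full dataset. Ties are broken by the first point
#' encountered in lexicographic grid order. The full published grid is
#' combinatorially huge (millions of points), so the search refuses any
#' grid larger than `max_points` and more than `max_free_axes` axes with
#' several values each; pin the remaining axes via `fixed`, mirroring
#' the one-axis-at-a-time sensitivity analysis.
#'
#' @param space A [search_space_grid()].
#' @param dataset A `labeled_dataset`.
#' @param k_folds Number of CV folds (default 5).
#' @param seed Integer seed (folds, training).
#' @param fixed Named list of pinned hyperparameter values.
#' @param max_points Refusal threshold on grid cardinality.
#' @param max_free_axes Maximum number of non-pinned multi-valued axes.
#' @return Object of class `search_result`: `best_config`, `best_score`,
#'   `trials` (one row per grid point with fold scores and mean), and
#'   the refit `model`.
#' @export
grid_search <- function(space, dataset, k_folds = 5, seed = 1,
                        fixed = list(), max_points = 64,
                        max_free_axes = 3) {
  stopifnot(inherits(space, "search_space_grid"))
  if (k_folds < 2) stop("k_folds must be at least 2", call. = FALSE)
  axes <- unclass(space)
  axes[names(fixed)] <- lapply(fixed, function(v) v[1])
  free <- sum(vapply(axes, length, integer(1)) > 1)
  n_points <- prod(vapply(axes, length, integer(1)))
  if (free > max_free_axes || n_points > max_points) {
    stop("grid has ", n_points, " points over ", free, " free axes; ",
         "pin axes via `fixed` (caps: ", max_points, " points, ",
         max_free_axes, " free axes)", call. = FALSE)
  }
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  fold <- stratified_folds(dataset$y, k_folds)
  trials <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config_from_values(grid[i, ])
    t0 <- proc.time()[["elapsed"]]
    set.seed(seed + i)
    scores <- cv_score(cfg, dataset, k_folds, fold)
    trials[[i]] <- data.frame(trial = i, grid[i, , drop = FALSE],
                              mean_score = mean(scores),
                              t(stats::setNames(scores, paste0("fold", seq_len(k_folds)))),
                              wall_s = proc.time()[["elapsed"]] - t0,
                              row.names = NULL)
  }
  trials <- do.call(rbind, trials)
  finish_search(trials, axes_names = names(axes), dataset, seed)
}

finish_search <- function(trials, axes_names, dataset, seed) {
  best <- which.max(trials$mean_score)   # first max wins ties
  best_config <- config_from_values(trials[best, axes_names])
  set.seed(seed)
  model <- suppressWarnings(oxi_cnn(dataset, config = best_config))
  structure(list(
    best_config = best_config,
    best_score = trials$mean_score[best],
    trials = trials,
    model = model
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>", nrow(x$trials), "trials; best CV accuracy",
      format(x$best_score, digits = 4), "\n")
  invisible(x)
}

# ---- Gaussian-process surrogate + expected improvement ----------------
# Small isotropic RBF-kernel GP on inputs scaled to the unit box; used
# as the probabilistic surrogate of the sequential Bayesian search.

gp_fit <- function(X, y, lengthscale = NULL, nugget = 1e-6) {
  d <- ncol(X)
  if (is.null(lengthscale)) lengthscale <- 0.3 * sqrt(d)
  sf2 <- max(stats::var(y), 1e-10)
  K <- sf2 * exp(-as.matrix(stats::dist(X))^2 / (2 * lengthscale^2))
  diag(K) <- diag(K) + nugget * sf2 + 1e-10
  L <- chol(K)
  mu <- mean(y)
  alpha <- backsolve(L, backsolve(L, y - mu, transpose = TRUE))
  list(X = X, L = L, alpha = alpha, mu = mu, sf2 = sf2, ls = lengthscale)
}

gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), `+`) -
    2 * Xnew %*% t(gp$X)
  d2[d2 < 0] <- 0
  Ks <- gp$sf2 * exp(-d2 / (2 * gp$ls^2))
  mean <- gp$mu + Ks %*% gp$alpha
  v <- backsolve(gp$L, t(Ks), transpose = TRUE)
  var <- pmax(gp$sf2 - colSums(v^2), 1e-12)
  list(mean = drop(mean), sd = sqrt(var))
}

expected_improvement <- function(mean, sd, best) {
  z <- (mean - best) / sd
  (mean - best) * stats::pnorm(z) + sd * stats::dnorm(z)
}

# Map unit-box coordinates to hyperparameter values and back.
unit_to_values <- function(u, space) {
  vals <- list()
  for (j in seq_along(space)) {
    b <- space[[j]]
    v <- if (b$type == "log-real") {
      exp(log(b$low) + u[j] * (log(b$high) - log(b$low)))
    } else {
      b$low + u[j] * (b$high - b$low)
    }
    if (b$type == "integer") v <- round(v)
    vals[[names(space)[j]]] <- min(max(v, b$low), b$high)
  }
  vals
}

#' Sequential Bayesian hyperparameter optimization
#'
#' Maximizes cross-validated accuracy (or an arbitrary objective) over a
#' bounded box with a Gaussian-process surrogate and expected-improvement
#' acquisition. Integer axes are proposed by rounding; the learning rate
#' is searched on a log scale. The first `n_init` trials are a seeded
#' space-filling design, after which each proposal maximizes expected
#' improvement over a random candidate set. The trial sequence is
#' deterministic under `seed`.
#'
#' @param space A [search_space_bounds()].
#' @param dataset A `labeled_dataset` (ignored when `objective` is given).
#' @param n_trials Total number of trials (at least 5).
#' @param k_folds CV folds for the default objective.
#' @param seed Integer seed.
#' @param objective Optional function `f(values_list) -> score` to
#'   maximize instead of the CV objective.
#' @param n_init Number of initial space-filling trials.
#' @param n_candidates Random candidates scored per EI proposal.
#' @return A `search_result` (with `model = NULL` when a custom
#'   objective was used).
#' @export
bayes_opt <- function(space, dataset = NULL, n_trials = 25, k_folds = 5,
                      seed = 1, objective = NULL,
                      n_init = max(4, min(8, n_trials - 1)),
                      n_candidates = 500) {
  stopifnot(inherits(space, "search_space_bounds"))
  if (n_trials < 5) stop("n_trials must be at least 5", call. = FALSE)
  d <- length(space)
  set.seed(seed)
  fold <- NULL
  if (is.null(objective)) {
    if (is.null(dataset)) stop("provide a dataset or an objective", call. = FALSE)
    fold <- stratified_folds(dataset$y, k_folds)
    objective <- function(values) {
      mean(cv_score(config_from_values(values), dataset, k_folds, fold))
    }
  }
  U <- matrix(NA_real_, n_trials, d)
  y <- numeric(n_trials)
  recs <- vector("list", n_trials)
  # stratified random initial design
  U[seq_len(n_init), ] <- vapply(seq_len(d), function(j) {
    (sample(n_init) - stats::runif(n_init)) / n_init
  }, numeric(n_init))
  for (i in seq_len(n_trials)) {
    if (i > n_init) {
      gp <- gp_fit(U[seq_len(i - 1), , drop = FALSE], y[seq_len(i - 1)])
      cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
      # local refinements around the incumbent
      inc <- U[which.max(y[seq_len(i - 1)]), ]
      loc <- matrix(rep(inc, each = 50), 50, d) +
        matrix(stats::rnorm(50 * d, 0, 0.05), 50, d)
      cand <- rbind(cand, pmin(pmax(loc, 0), 1))
      pr <- gp_predict(gp, cand)
      ei <- expected_improvement(pr$mean, pr$sd, max(y[seq_len(i - 1)]))
      U[i, ] <- cand[which.max(ei), ]
    }
    values <- unit_to_values(U[i, ], space)
    t0 <- proc.time()[["elapsed"]]
    y[i] <- objective(values)
    recs[[i]] <- data.frame(trial = i, as.data.frame(values),
                            mean_score = y[i],
                            wall_s = proc.time()[["elapsed"]] - t0,
                            row.names = NULL)
  }
  trials <- do.call(rbind, recs)
  if (!is.null(dataset) && !is.null(fold)) {
    finish_search(trials, names(space), dataset, seed)
  } else {
    best <- which.max(trials$mean_score)
    structure(list(
      best_config = as.list(trials[best, names(space)]),
      best_score = trials$mean_score[best],
      trials = trials,
      model = NULL
    ), class = "search_result")
  }
}

#' Two-stage coarse-then-fine search
#'
#' Stage 1 searches the full box; stage 2 re-centers a box of width
#' shrunk by `stage2_shrink` on the stage-1 optimum (clipped into the
#' original bounds, log-scale axes shrunk in log space) and searches
#' again. Trials are concatenated and the overall best returned, so the
#' refinement can never degrade the stage-1 best.
#'
#' @param space A [search_space_bounds()].
#' @param dataset A `labeled_dataset` (or `NULL` with `objective`).
#' @param stage2_shrink Fraction of the original width kept in stage 2.
#' @param n_trials Trials per stage.
#' @param seed Integer seed.
#' @param objective Optional objective, as in [bayes_opt()].
#' @param ... Passed on to [bayes_opt()].
#' @return A `search_result` with an extra `stage2_space` element.
#' @export
coarse_then_fine <- function(space, dataset = NULL, stage2_shrink = 0.25,
                             n_trials = 15, seed = 1, objective = NULL, ...) {
  stopifnot(inherits(space, "search_space_bounds"))
  if (stage2_shrink <= 0 || stage2_shrink >= 1) {
    stop("stage2_shrink must lie in (0, 1)", call. = FALSE)
  }
  s1 <- bayes_opt(space, dataset, n_trials = n_trials, seed = seed,
                  objective = objective, ...)
  best <- s1$best_config
  space2 <- space
  for (nm in names(space)) {
    b <- space[[nm]]
    v <- if (inherits(best, "cnn_config")) best[[nm]] else best[[nm]]
    if (b$type == "log-real") {
      w <- (log(b$high) - log(b$low)) * stage2_shrink / 2
      lo <- exp(max(log(b$low), log(v) - w))
      hi <- exp(min(log(b$high), log(v) + w))
    } else {
      w <- (b$high - b$low) * stage2_shrink / 2
      lo <- max(b$low, v - w)
      hi <- min(b$high, v + w)
    }
    if (hi <= lo) { lo <- b$low; hi <- b$high }  # degenerate: keep original
    space2[[nm]]$low <- lo
    space2[[nm]]$high <- hi
  }
  s2 <- bayes_opt(space2, dataset, n_trials = n_trials, seed = seed + 1,
                  objective = objective, ...)
  s1$trials$stage <- 1L
  s2$trials$stage <- 2L
  trials <- rbind(s1$trials, s2$trials)
  out <- if (s2$best_score >= s1$best_score) s2 else s1
  out$trials <- trials
  out$stage2_space <- space2
  out
}
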