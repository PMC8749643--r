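#' Named spectral region presets
#'
#' The twelve channels split into a visible "first region" (450-610 nm),
#' whose transmitted curves are nearly indistinguishable across SpO2,
#' and a red/NIR "second region" (650-860 nm), whose curves separate
#' well; each region further splits into four three-channel sub-regions
#' used by the ablation study.
#'
#' @format Named list; each element is a `region_spec`: a list with
#'   `name` and ascending `centers_nm`.
#' @export
SPO2_REGIONS <- local({
  mk <- function(name, centers) {
    structure(list(name = name, centers_nm = centers), class = "region_spec")
  }
  list(
    FIRST  = mk("FIRST",  c(450, 500, 550, 570, 600, 610)),
    SECOND = mk("SECOND", c(650, 680, 730, 760, 810, 860)),
    FULL   = mk("FULL",   c(450, 500, 550, 570, 600, 610,
                            650, 680, 730, 760, 810, 860)),
    S11 = mk("S11", c(450, 500, 550)),
    S12 = mk("S12", c(500, 550, 570)),
    S13 = mk("S13", c(570, 600, 610)),
    S14 = mk("S14", c(450, 570, 610)),
    S21 = mk("S21", c(650, 680, 730)),
    S22 = mk("S22", c(730, 760, 810)),
    S23 = mk("S23", c(760, 810, 860)),
    S24 = mk("S24", c(650, 760, 860))
  )
})

#' Resolve a region specification
#'
#' @param region A preset name (`"FIRST"`, `"SECOND"`, `"FULL"`,
#'   `"S11"`..`"S14"`, `"S21"`..`"S24"`), a `region_spec`, or a numeric
#'   vector of channel centers.
#' @return A `region_spec` with ascending centers drawn from the twelve
#'   supported channels.
#' @export
#' @examples
#' region_spec("SECOND")$centers_nm
region_spec <- function(region) {
  if (inherits(region, "region_spec")) return(region)
  if (is.character(region) && length(region) == 1) {
    if (!region %in% names(SPO2_REGIONS)) {
      stop("unknown region preset '", region, "'; known: ",
           paste(names(SPO2_REGIONS), collapse = ", "), call. = FALSE)
    }
    return(SPO2_REGIONS[[region]])
  }
  if (is.numeric(region) && length(region) > 0) {
    if (!all(region %in% CHANNEL_CENTERS)) {
      stop("region centers must be drawn from the 12 supported channels",
           call. = FALSE)
    }
    return(structure(list(name = "custom", centers_nm = sort(region)),
                     class = "region_spec"))
  }
  stop("region must be a preset name, a region_spec, or channel centers",
       call. = FALSE)
}

#' Min-max normalize one spectral curve to \[0, 1\]
#'
#' Each curve is rescaled by its own extremes,
#' `(I - I_min) / (I_max - I_min)`, so the minimum channel maps to 0 and
#' the maximum to 1. A constant (degenerate) curve maps to all zeros with
#' a warning of class `oxispec_degenerate_curve` rather than an error,
#' so pathological frames do not abort batch runs.
#'
#' @param raw_values Numeric vector of per-channel intensities
#'   (at least 2 channels).
#' @return Numeric vector of the same length in \[0, 1\].
#' @export
#' @examples
#' normalize_spectrum(c(2, 4, 6))         # 0.0 0.5 1.0
#' normalize_spectrum(c(10, 30, 20, 40))  # 0 2/3 1/3 1
normalize_spectrum <- function(raw_values) {
  if (!is.numeric(raw_values) || length(raw_values) < 2) {
    stop("need at least 2 channels to normalize", call. = FALSE)
  }
  rng <- range(raw_values)
  if (rng[1] == rng[2]) {
    warning(warningCondition(
      "degenerate constant curve normalized to zeros",
      class = "oxispec_degenerate_curve"))
    out <- raw_values * 0
  } else {
    out <- (raw_values - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Restrict a frame, frame list, or dataset to a spectral region
#'
#' Columns (or channels) are restricted to and ordered by the region's
#' ascending centers; labels are preserved. A missing channel is a
#' schema error naming the first missing center.
#'
#' @param x A `spectral_frame`, a list of them, or a `labeled_dataset`.
#' @param region See [region_spec()].
#' @return Same kind of object as `x`, restricted to the region.
#' @export
select_region <- function(x, region) {
  region <- region_spec(region)
  nm <- paste0("nm", region$centers_nm)
  if (inherits(x, "spectral_frame")) {
    missing <- setdiff(nm, names(x$dc))
    if (length(missing)) {
      stop("channel ", missing[1], " not present in frame", call. = FALSE)
    }
    x$dc <- x$dc[nm]
    x$ac <- x$ac[nm]
    x$flag <- x$flag[nm]
    x$channels <- x$channels[x$channels$center_nm %in% region$centers_nm, ]
    return(x)
  }
  if (is.list(x) && length(x) && inherits(x[[1]], "spectral_frame")) {
    return(lapply(x, select_region, region = region))
  }
  if (inherits(x, "labeled_dataset")) {
    missing <- setdiff(nm, colnames(x$X))
    if (length(missing)) {
      stop("channel ", missing[1], " not present in dataset", call. = FALSE)
    }
    x$X <- x$X[, nm, drop = FALSE]
    x$region <- region
    return(x)
  }
  stop("select_region expects a spectral_frame, a list of frames, or a labeled_dataset",
       call. = FALSE)
}

#' Expand one normalized spectrum by uniform multiplicative noise
#'
#' Each output row is the input curve with independent per-channel
#' perturbations `value * (1 + u)`, `u ~ Uniform(-noise_ratio,
#' +noise_ratio)`, clipped back to \[0, 1\]. This is the augmentation
#' that expands each concentration's representative curve to the rows
#' the network trains on.
#'
#' @param spectrum Normalized numeric vector (values in \[0, 1\]).
#' @param noise_ratio Fractional noise amplitude in \[0, 0.10\]
#'   (the studied range: 0, 1, 2, 5 and 10 percent).
#' @param n_rows Number of rows to generate (default 1000).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return `n_rows` x `length(spectrum)` numeric matrix.
#' @export
#' @examples
#' a <- augment_spectrum(c(0, 0.5, 1), noise_ratio = 0.02, n_rows = 5, seed = 1)
#' dim(a)
augment_spectrum <- function(spectrum, noise_ratio, n_rows = 1000, seed = NULL) {
  if (noise_ratio < 0 || noise_ratio > 0.10) {
    stop("noise_ratio must lie in [0, 0.10]", call. = FALSE)
  }
  if (n_rows < 1) stop("n_rows must be positive", call. = FALSE)
  if (any(spectrum < 0 | spectrum > 1)) {
    stop("spectrum must be normalized to [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- length(spectrum)
  u <- matrix(stats::runif(n_rows * p, -noise_ratio, noise_ratio), n_rows, p)
  out <- sweep(1 + u, 2, spectrum, `*`)
  out[out < 0] <- 0
  out[out > 1] <- 1
  colnames(out) <- names(spectrum)
  out
}

#' Assemble a labeled training dataset from one frame per concentration
#'
#' For each label: restrict the frame's DC intensities to the region,
#' min-max normalize the curve, and expand it to `n_rows_per_label` rows
#' by uniform noise augmentation; rows are then shuffled. Degenerate
#' (constant) curves are tolerated and counted in a single summary
#' warning.
#'
#' @param frames List of labeled `spectral_frame`s, exactly one per label.
#' @param region See [region_spec()].
#' @param noise_ratio Fractional augmentation noise in \[0, 0.10\].
#' @param n_rows_per_label Rows per concentration (default 1000).
#' @param seed Integer seed controlling augmentation and shuffling.
#' @return An object of class `labeled_dataset`: list with matrix `X`
#'   (rows x region channels, values in \[0, 1\]), integer labels `y`,
#'   ascending `label_vector`, `region`, `noise_ratio`, `seed`.
#' @export
#' @examples
#' frames <- generate_sweep(cfg = simulator_config(), seed = 1)
#' ds <- build_dataset(frames, "SECOND", noise_ratio = 0.02,
#'                     n_rows_per_label = 10, seed = 1)
#' dim(ds$X)
build_dataset <- function(frames, region, noise_ratio = 0.02,
                          n_rows_per_label = 1000, seed = 1) {
  region <- region_spec(region)
  labels <- vapply(frames, function(f) f$spo2, numeric(1))
  dup <- unique(labels[duplicated(labels)])
  if (length(dup)) {
    stop("duplicate labels in frames: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(labels))) stop("all frames must carry a label", call. = FALSE)
  ord <- order(labels)
  frames <- frames[ord]
  labels <- labels[ord]

  set.seed(seed)
  n_degenerate <- 0L
  blocks <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- select_region(frames[[i]], region)
    values <- withCallingHandlers(
      normalize_spectrum(fr$dc),
      oxispec_degenerate_curve = function(w) {
        n_degenerate <<- n_degenerate + 1L
        invokeRestart("muffleWarning")
      })
    blocks[[i]] <- augment_spectrum(values, noise_ratio,
                                    n_rows = n_rows_per_label, seed = NULL)
  }
  if (n_degenerate > 0) {
    warning(warningCondition(
      paste0(n_degenerate, " of ", length(frames),
             " curves were degenerate (constant) and normalized to zeros"),
      class = "oxispec_degenerate_dataset"))
  }
  X <- do.call(rbind, blocks)
  y <- rep(labels, each = n_rows_per_label)
  idx <- sample.int(nrow(X))
  structure(list(
    X = X[idx, , drop = FALSE],
    y = y[idx],
    label_vector = labels,
    region = region,
    noise_ratio = noise_ratio,
    seed = seed
  ), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$X), " rows x ", ncol(x$X),
      " channels (region ", x$region$name, "), ",
      length(x$label_vector), " labels, noise ",
      x$noise_ratio * 100, "%\n", sep = "")
  invisible(x)
}
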