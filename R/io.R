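#' Write spectral frames to CSV
#'
#' Schema: `timestamp,label,dc_450,...,dc_860,ac_450,...,ac_860` with
#' channel columns in ascending wavelength order. Intensities are ADC
#' integers, so the round trip through [read_frames()] is lossless.
#'
#' @param frames List of `spectral_frame`s sharing a channel set.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  stopifnot(length(frames) > 0)
  centers <- frames[[1]]$channels$center_nm
  df <- do.call(rbind, lapply(frames, function(f) {
    if (!identical(f$channels$center_nm, centers)) {
      stop("all frames must share the same channel set", call. = FALSE)
    }
    row <- data.frame(timestamp = f$timestamp,
                      label = if (is.null(f$spo2) || is.na(f$spo2)) NA else f$spo2)
    for (c in centers) row[[paste0("dc_", c)]] <- f$dc[[paste0("nm", c)]]
    for (c in centers) row[[paste0("ac_", c)]] <- f$ac[[paste0("nm", c)]]
    row
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectral frames from CSV
#'
#' Validates the schema written by [write_frames()]: known columns only,
#' strictly ascending channel order, labels inside \[81, 99\] (or NA).
#' Violations raise a schema error naming the first offending column or
#' row. An empty file with a valid header yields an empty list.
#'
#' @param path CSV path.
#' @return List of `spectral_frame`s.
#' @export
read_frames <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- names(df)
  if (!identical(cols[1:2], c("timestamp", "label"))) {
    stop("schema error: first columns must be timestamp,label", call. = FALSE)
  }
  dc_cols <- grep("^dc_", cols, value = TRUE)
  ac_cols <- grep("^ac_", cols, value = TRUE)
  other <- setdiff(cols, c("timestamp", "label", dc_cols, ac_cols))
  if (length(other)) {
    stop("schema error: unknown column '", other[1], "'", call. = FALSE)
  }
  dc_centers <- as.numeric(sub("^dc_", "", dc_cols))
  ac_centers <- as.numeric(sub("^ac_", "", ac_cols))
  if (any(diff(dc_centers) <= 0)) {
    bad <- dc_cols[which(diff(dc_centers) <= 0)[1] + 1]
    stop("schema error: channel columns out of ascending order at '",
         bad, "'", call. = FALSE)
  }
  if (!identical(dc_centers, ac_centers)) {
    stop("schema error: dc and ac channel sets differ", call. = FALSE)
  }
  channels <- sensor_channels(dc_centers)
  nm <- paste0("nm", dc_centers)
  lapply(seq_len(nrow(df)), function(i) {
    lab <- df$label[i]
    if (!is.na(lab) && (lab < 81 || lab > 99)) {
      stop("schema error: label ", lab, " outside [81, 99] at row ", i,
           call. = FALSE)
    }
    structure(list(
      channels = channels,
      dc = stats::setNames(as.numeric(df[i, dc_cols]), nm),
      ac = stats::setNames(as.numeric(df[i, ac_cols]), nm),
      spo2 = if (is.na(lab)) NA_real_ else as.numeric(lab),
      timestamp = df$timestamp[i],
      flag = stats::setNames(rep("ok", length(nm)), nm)
    ), class = "spectral_frame")
  })
}

#' Write a labeled dataset to CSV with a JSON metadata sidecar
#'
#' The CSV has columns `label,nm<center>,...` for the active region;
#' normalized intensities are written with 17 significant digits so the
#' round trip through [read_dataset()] is bit-exact, and identical seeds
#' always produce byte-identical files. Provenance (region, noise ratio,
#' seed, row counts, label vector) goes to `<path>.meta.json`.
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  X <- dataset$X
  body <- cbind(format(dataset$y, trim = TRUE, scientific = FALSE),
                matrix(sprintf("%.17g", X), nrow(X), ncol(X)))
  lines <- c(paste(c("label", colnames(X)), collapse = ","),
             apply(body, 1, paste, collapse = ","))
  writeLines(lines, path)
  meta <- list(region = dataset$region$name,
               centers_nm = dataset$region$centers_nm,
               noise_ratio = dataset$noise_ratio,
               seed = dataset$seed,
               n_rows = nrow(X),
               label_vector = dataset$label_vector)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a labeled dataset written by [write_dataset()]
#'
#' @param path CSV path (expects the `<path>.meta.json` sidecar).
#' @return A `labeled_dataset`.
#' @export
read_dataset <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  structure(list(
    X = X,
    y = as.numeric(df$label),
    label_vector = meta$label_vector,
    region = if (meta$region %in% names(SPO2_REGIONS)) {
      region_spec(meta$region)
    } else {
      region_spec(meta$centers_nm)
    },
    noise_ratio = meta$noise_ratio,
    seed = meta$seed
  ), class = "labeled_dataset")
}
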