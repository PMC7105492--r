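# Serialization layer: images as multi-page TIFF plus a JSON sidecar
# (pixel size, intensity scale, ground truth), sweeps and series as CSV
# plus a JSON sidecar. Ground truth round-trips unchanged; jsonlite is used
# with full precision (digits = NA).

# Encode/decode ground-truth lists, replacing logical rasters by index
# run-length so the sidecar stays plain text.
encode_gt <- function(gt) {
  lapply(gt, function(v) {
    if (is.matrix(v) && is.logical(v))
      list(`_mask_dim` = dim(v), `_mask_which` = which(v))
    else if (is.matrix(v)) list(`_mat_dim` = dim(v), `_mat_data` = as.vector(v))
    else v
  })
}

decode_gt <- function(gt) {
  lapply(gt, function(v) {
    if (is.list(v) && !is.null(v$`_mask_dim`)) {
      m <- matrix(FALSE, v$`_mask_dim`[1], v$`_mask_dim`[2])
      m[v$`_mask_which`] <- TRUE
      m
    } else if (is.list(v) && !is.null(v$`_mat_dim`)) {
      matrix(v$`_mat_data`, v$`_mat_dim`[1], v$`_mat_dim`[2])
    } else if (is.list(v)) v else unlist(v)
  })
}

#' Write a labeled image as multi-page TIFF with a JSON sidecar
#'
#' @param limg a `labeled_image`.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_labeled_image <- function(limg, path) {
  stopifnot(inherits(limg, "labeled_image"))
  scale <- max(1e-12, max(vapply(limg$planes, max, numeric(1))))
  tiff::writeTIFF(lapply(limg$planes, function(p) pmax(p, 0) / scale),
                  path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = limg$pixel_size_um,
               intensity_scale = scale,
               ground_truth = encode_gt(limg$ground_truth))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a labeled image written by [write_labeled_image()]
#'
#' @param path TIFF path with `<path>.json` sidecar.
#' @return a `labeled_image`.
#' @export
read_labeled_image <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  planes <- lapply(planes, function(p) p * meta$intensity_scale)
  structure(list(planes = planes, pixel_size_um = meta$pixel_size_um,
                 ground_truth = decode_gt(meta$ground_truth), params = NULL),
            class = "labeled_image")
}

#' Write a sweep set as CSV plus a JSON sidecar
#'
#' The CSV holds the time column and one column per sweep, named
#' `<condition>_<n_stim>.<sweep>`; the sidecar holds sampling rate,
#' stimulus times, baseline window, and ground truth.
#'
#' @param sweeps a `sweep_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_set <- function(sweeps, path) {
  stopifnot(inherits(sweeps, "sweep_set"))
  cols <- list(time = sweeps$time)
  for (nm in names(sweeps$traces)) {
    m <- as.matrix(sweeps$traces[[nm]])
    for (k in seq_len(ncol(m))) cols[[paste0(nm, ".", k)]] <- m[, k]
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  meta <- list(sampling_rate = sweeps$sampling_rate,
               stim_times = sweeps$stim_times,
               baseline_window = sweeps$baseline_window,
               ground_truth = encode_gt(sweeps$ground_truth))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sweep set written by [write_sweep_set()]
#'
#' @param path CSV path with `<path>.json` sidecar.
#' @return a `sweep_set`.
#' @export
read_sweep_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  keys <- unique(sub("\\.[0-9]+$", "", setdiff(names(df), "time")))
  traces <- lapply(keys, function(k) {
    as.matrix(df[grep(paste0("^", k, "\\.[0-9]+$"), names(df))])
  })
  names(traces) <- keys
  gt <- decode_gt(meta$ground_truth)
  structure(list(time = df$time, sampling_rate = meta$sampling_rate,
                 stim_times = meta$stim_times,
                 baseline_window = meta$baseline_window,
                 traces = traces, ground_truth = gt, params = NULL),
            class = "sweep_set")
}

#' Write a coupled network as CSV
#'
#' @param network a `coupled_network`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coupled_network <- function(network, path) {
  utils::write.csv(as.data.frame(network), path, row.names = FALSE)
  invisible(path)
}

#' Read a coupled-network CSV
#'
#' @param path CSV with columns `cell_id`, `x`, `y`, `z`, `fluorescence`,
#'   `is_patched`.
#' @return a `coupled_network` data frame.
#' @export
read_coupled_network <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z", "fluorescence") %in% names(df)))
  class(df) <- c("coupled_network", "data.frame")
  df
}
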