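# Dataset semantics: field-of-view / timestamp indexing, timestamp-range
# noise levels, input-reference pairing (reference = timestamp 1), the
# last-N-FOV train/test split, and normalized pair loading from TIFF.

#' Timestamp range of a noise level
#'
#' The published labels: level 1 covers timestamps 26-50, level 2 covers
#' 76-100, level 3 covers 126-150, level 4 covers 176-200. Noise increases
#' with the timestamp because of photobleaching.
#'
#' @param level Integer 1-4.
#' @return Length-2 integer vector `c(lo, hi)` (inclusive).
#' @export
noise_level_timestamps <- function(level) {
  ranges <- list(`1` = c(26L, 50L), `2` = c(76L, 100L),
                 `3` = c(126L, 150L), `4` = c(176L, 200L))
  key <- as.character(level)
  if (length(level) != 1L || is.na(key) || !key %in% names(ranges)) {
    stop("noise level must be one of 1, 2, 3, 4")
  }
  ranges[[key]]
}

timestamp_noise_level <- function(t) {
  for (lv in 1:4) {
    r <- noise_level_timestamps(lv)
    if (t >= r[1] && t <= r[2]) return(as.character(lv))
  }
  "other"
}

#' Count raw SIM images in an acquisition
#'
#' One stack of `frames_per_timestamp` raw frames (phase/orientation
#' combinations) per timestamp per FOV, so the total is the plain product.
#'
#' @param n_fovs,n_timestamps,frames_per_timestamp Nonnegative counts.
#' @return The product, as a double (can exceed integer range).
#' @export
count_raw_images <- function(n_fovs, n_timestamps, frames_per_timestamp = 15) {
  if (any(c(n_fovs, n_timestamps, frames_per_timestamp) < 0)) {
    stop("counts must be nonnegative")
  }
  as.numeric(n_fovs) * n_timestamps * frames_per_timestamp
}

#' Build the (noisy input, reference) pairing of a dataset
#'
#' For every FOV, every timestamp in `input_range` (clipped to the FOV's
#' own timestamp count) becomes an input paired with the FOV's timestamp-1
#' reference. Records are ordered by FOV, then timestamp, and carry the
#' noise-level label of their timestamp.
#'
#' @param fov_ids Ordered vector of 1-based FOV indices (acquisition order;
#'   "last N FOVs" in [split_train_test()] refers to this order).
#' @param timestamps_per_fov Named (by FOV id) or positionally matched
#'   vector of per-FOV timestamp counts.
#' @param input_range Length-2 inclusive timestamp range `c(lo, hi)`,
#'   `lo >= 2` (timestamp 1 is the reference and cannot be its own input).
#' @param reference_timestamp Must be 1.
#' @param data_dir Optional dataset directory; when given, file paths
#'   `fov{F}_t{T}.tif` are filled in.
#' @return A `dataset_manifest`: data frame with columns `fov_id`,
#'   `input_timestamp`, `reference_timestamp`, `input_path`,
#'   `reference_path`, `noise_level`, plus a `fov_ids` attribute.
#' @export
build_denoise_pairs <- function(fov_ids, timestamps_per_fov, input_range,
                                reference_timestamp = 1L, data_dir = NULL) {
  if (reference_timestamp != 1L) stop("the reference is timestamp 1")
  lo <- input_range[1]; hi <- input_range[2]
  if (lo < 2L) stop("input range must start at timestamp >= 2")
  if (hi < lo) stop("empty input range")
  if (is.null(names(timestamps_per_fov))) {
    timestamps_per_fov <- stats::setNames(timestamps_per_fov, fov_ids)
  }
  rows <- list()
  for (f in fov_ids) {
    Tf <- timestamps_per_fov[[as.character(f)]]
    hi_f <- min(hi, Tf)
    if (hi_f < lo) next
    ts <- seq.int(lo, hi_f)
    rows[[length(rows) + 1L]] <- data.frame(
      fov_id = as.integer(f), input_timestamp = as.integer(ts),
      reference_timestamp = 1L,
      input_path = if (is.null(data_dir)) NA_character_ else
        file.path(data_dir, sprintf("fov%d_t%d.tif", f, ts)),
      reference_path = if (is.null(data_dir)) NA_character_ else
        file.path(data_dir, sprintf("fov%d_t1.tif", f)),
      noise_level = vapply(ts, timestamp_noise_level, character(1)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fov_id = integer(), input_timestamp = integer(),
               reference_timestamp = integer(), input_path = character(),
               reference_path = character(), noise_level = character())
  rownames(out) <- NULL
  attr(out, "fov_ids") <- as.integer(fov_ids)
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Pair manifest from a generated dataset directory
#'
#' Reads the `manifest.csv` written by [generate_dataset()] and builds the
#' input/reference pairing for the given timestamp range.
#'
#' @param data_dir Dataset directory.
#' @param input_range Inclusive timestamp range for the noisy inputs.
#' @export
pairs_from_dataset <- function(data_dir, input_range) {
  mf <- utils::read.csv(file.path(data_dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  fovs <- unique(mf$fov)
  tpf <- vapply(fovs, function(f) max(mf$timestamp[mf$fov == f]), numeric(1))
  build_denoise_pairs(fovs, stats::setNames(tpf, fovs), input_range,
                      data_dir = data_dir)
}

#' Split a manifest into train and test sets by FOV
#'
#' The last `n_test_fovs` FOVs (in `fov_ids` order) form the test set; all
#' other records form the training set. The split is FOV-disjoint: no field
#' of view contributes to both sides.
#'
#' @param manifest A `dataset_manifest`.
#' @param n_test_fovs Number of held-out FOVs (default 20, the published
#'   split).
#' @param policy Only `"last"` is defined.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(manifest, n_test_fovs = 20L, policy = "last") {
  stopifnot(identical(policy, "last"))
  fov_ids <- attr(manifest, "fov_ids")
  if (is.null(fov_ids)) fov_ids <- unique(manifest$fov_id)
  if (n_test_fovs >= length(fov_ids)) {
    stop("n_test_fovs must be smaller than the number of FOVs")
  }
  test_fovs <- if (n_test_fovs > 0L) {
    fov_ids[seq.int(length(fov_ids) - n_test_fovs + 1L, length(fov_ids))]
  } else integer()
  is_test <- manifest$fov_id %in% test_fovs
  train <- manifest[!is_test, , drop = FALSE]
  test <- manifest[is_test, , drop = FALSE]
  attr(train, "fov_ids") <- setdiff(fov_ids, test_fovs)
  attr(test, "fov_ids") <- test_fovs
  class(train) <- class(test) <- c("dataset_manifest", "data.frame")
  list(train = train, test = test)
}

#' Load one (input, reference) image pair, jointly normalized
#'
#' Both TIFFs are read as integer counts and divided by the maximum of the
#' reference (1 if the reference is all zero), so the pair stays on a common
#' scale with the reference peak at 1; input values above 1 are allowed.
#' Negative values are clipped to 0.
#'
#' @param record One-row slice of a `dataset_manifest` (or a list with
#'   `input_path` and `reference_path`).
#' @return List with float matrices `input` and `reference`, and `scale`.
#' @export
load_pair <- function(record) {
  input <- read_count_tiff(record$input_path)
  reference <- read_count_tiff(record$reference_path)
  if (!all(dim(input) == dim(reference))) {
    stop("input and reference have different shapes: ",
         record$input_path, " vs ", record$reference_path)
  }
  s <- max(reference)
  if (s <= 0) s <- 1
  list(input = pmax(input / s, 0), reference = pmax(reference / s, 0),
       scale = s)
}

#' Write a pair manifest to CSV
#'
#' @param manifest A `dataset_manifest`.
#' @param path Output CSV path.
#' @export
write_pair_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_manifest
#' @param path CSV path to read.
#' @export
read_pair_manifest <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(out, "fov_ids") <- unique(out$fov_id)
  class(out) <- c("dataset_manifest", "data.frame")
  out
}
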