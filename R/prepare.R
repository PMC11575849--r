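# Data preparation for the classifier: slight smoothing (three kernel
# variants as data augmentation), 10x downsampling, and splitting each
# record into six 10 s segments.

#' Default smoothing kernels for augmentation
#'
#' Centred moving-average widths (samples at the raw 1000 Hz rate) for the
#' three augmentation variants k1/k2/k3.
#' @export
SMOOTH_KERNELS <- c(k1 = 5L, k2 = 15L, k3 = 25L)

#' Centred moving-average smoothing
#'
#' Mean-preserving smoother with a shrinking window at the boundaries, so
#' the output length equals the input length and a constant series is
#' unchanged.
#'
#' @param x numeric series.
#' @param kernel_id one of `"k1"`, `"k2"`, `"k3"`, or an odd integer width.
#' @param kernels named width map (default [SMOOTH_KERNELS]).
#' @return Smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, kernel_id = "k1", kernels = SMOOTH_KERNELS) {
  width <- if (is.numeric(kernel_id)) as.integer(kernel_id)
  else {
    if (!kernel_id %in% names(kernels))
      stop_domain("unknown smoothing kernel: ", kernel_id)
    kernels[[kernel_id]]
  }
  if (width < 1L || width %% 2L == 0L)
    stop_domain("kernel width must be a positive odd integer")
  n <- length(x)
  h <- width %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Downsample by index thinning
#'
#' Keeps every `1 / fraction`-th sample (decimation, not block averaging):
#' a 60 000-sample record at `fraction = 0.1` becomes 6000 observations.
#'
#' @param x numeric series.
#' @param fraction fraction of samples to keep (default 0.1).
#' @return Thinned series. If the length is not divisible by the step, the
#'   remainder is dropped with a warning.
#' @export
downsample_series <- function(x, fraction = 0.1) {
  step <- round(1 / fraction)
  if (length(x) %% step != 0L)
    warning("series length not divisible by ", step,
            ": trailing remainder dropped", call. = FALSE)
  x[seq.int(1L, (length(x) %/% step) * step, by = step)]
}

#' Split a series into equal contiguous segments
#'
#' @param x numeric series; length must be divisible by `n_segments`.
#' @param n_segments number of parts (default 6, i.e. six 10 s windows of
#'   1000 observations from a 6000-observation record).
#' @return A matrix with `n_segments` columns, one segment per column,
#'   order preserved (column 1 is the earliest part).
#' @export
segment_series <- function(x, n_segments = 6L) {
  if (length(x) %% n_segments != 0L)
    stop_domain("series length ", length(x), " is not divisible by ",
                n_segments, " segments")
  matrix(x, ncol = n_segments)
}

#' Build the labelled, fold-assigned segment dataset
#'
#' Full preparation of an experiment bundle for cross-validation: for every
#' preserved-fish run and each smoothing kernel, the three force channels
#' (X and Y via the moment-arm conversion, Z direct) are smoothed,
#' downsampled to 10% and split into six 1000-sample segments; labels are
#' CS 0, CR 1, BR 2, BS 3. Segments are assigned to `n_folds` balanced
#' folds.
#'
#' Fold grouping (`group_by`):
#' * `"part"` (default): all three kernel variants of one 10 s part of one
#'   fish-treatment series share a fold, so no validation segment ever
#'   appears in training under a different smoothing kernel, and folds are
#'   exactly equal-sized and class-balanced (8064 segments split 2688 per
#'   fold, 672 per treatment per fold at the default 112 fish).
#' * `"series"`: all six parts of a series stay together as well; this is a
#'   stricter grouping but cannot produce exactly equal folds when the fish
#'   count per treatment is not divisible by the fold count.
#'
#' @param bundle an `experiment_bundle`.
#' @param kernels named kernel width map (default [SMOOTH_KERNELS]).
#' @param n_folds number of cross-validation folds (default 3).
#' @param fraction downsampling fraction (default 0.1).
#' @param n_segments parts per record (default 6).
#' @param group_by `"part"` or `"series"` (see Details).
#' @param seed seed for the fold assignment.
#' @param r lever length, m.
#' @return A list of class `segment_dataset`: `x` is a
#'   `(n_segments_total * seg_len) x 3` matrix in sample-major order,
#'   `meta` a `data.frame` with `segment_id, fish_id, treatment, label,
#'   kernel_id, part, fold`, plus `seg_len` and `n_channels`.
#' @export
build_dataset <- function(bundle, kernels = SMOOTH_KERNELS, n_folds = 3L,
                          fraction = 0.1, n_segments = 6L,
                          group_by = c("part", "series"), seed = 1L,
                          r = 0.10) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  group_by <- match.arg(group_by)
  keep <- vapply(bundle$runs, function(x) x$object_class == "preserved", TRUE)
  runs <- bundle$runs[keep]
  if (length(runs) == 0L) stop_domain("bundle contains no preserved-fish runs")

  n_raw <- length(runs[[1]]$Fz_N)
  step <- round(1 / fraction)
  seg_len <- (n_raw %/% step) %/% n_segments
  n_seg <- length(runs) * length(kernels) * n_segments
  x <- matrix(0, n_seg * seg_len, 3L)
  meta <- vector("list", length(runs) * length(kernels))

  seg_i <- 0L
  mi <- 0L
  for (run in runs) {
    chans <- list(torque_to_force(run$Mx_Nm, r),
                  torque_to_force(run$My_Nm, r),
                  run$Fz_N)
    for (ki in seq_along(kernels)) {
      prep <- lapply(chans, function(ch)
        segment_series(downsample_series(smooth_series(ch, kernels[[ki]]),
                                         fraction), n_segments))
      for (p in seq_len(n_segments)) {
        rows <- seg_i * seg_len + seq_len(seg_len)
        for (c_i in 1:3) x[rows, c_i] <- prep[[c_i]][, p]
        seg_i <- seg_i + 1L
      }
      mi <- mi + 1L
      meta[[mi]] <- data.frame(
        fish_id = run$fish_id, treatment = run$treatment,
        label = TREATMENT_LABELS[[run$treatment]],
        kernel_id = names(kernels)[ki], part = seq_len(n_segments),
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  meta$segment_id <- seq_len(nrow(meta))
  meta$fold <- assign_folds(meta, n_folds, group_by, seed)
  structure(list(x = x, meta = meta, seg_len = seg_len, n_channels = 3L),
            class = "segment_dataset")
}

# Balanced, seeded fold assignment on grouping keys; groups are split
# within treatment so every fold holds an equal share of each class.
assign_folds <- function(meta, n_folds, group_by, seed) {
  key <- if (group_by == "part")
    paste(meta$fish_id, meta$treatment, meta$part, sep = "|")
  else paste(meta$fish_id, meta$treatment, sep = "|")
  fold_of <- with_seed(seed, {
    out <- integer(0); nm <- character(0)
    for (tr in unique(meta$treatment)) {
      keys <- unique(key[meta$treatment == tr])
      keys <- sample(keys)
      f <- rep_len(seq_len(n_folds), length(keys))
      # rep_len cycles 1..n_folds so group counts differ by at most one
      out <- c(out, f); nm <- c(nm, keys)
    }
    stats::setNames(out, nm)
  })
  unname(fold_of[key])
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("<segment_dataset> %d segments of %d x %d (%s folds)\n",
              nrow(x$meta), x$seg_len, x$n_channels,
              paste(table(x$meta$fold), collapse = "/")))
  invisible(x)
}

#' Subset a segment dataset by segment index
#'
#' @param ds a `segment_dataset`.
#' @param idx integer vector of segment ids (rows of `ds$meta`).
#' @return A `segment_dataset` containing only those segments.
#' @export
dataset_subset <- function(ds, idx) {
  rows <- as.vector(outer(seq_len(ds$seg_len), (idx - 1L) * ds$seg_len, "+"))
  structure(list(x = ds$x[rows, , drop = FALSE],
                 meta = ds$meta[idx, , drop = FALSE],
                 seg_len = ds$seg_len, n_channels = ds$n_channels),
            class = "segment_dataset")
}
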