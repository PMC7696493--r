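# Per-sample 5-D feature vectors [kx, ky, hx, hy, a] with phase labels.
# Features are instantaneous channel values -- no windowed aggregation --
# because the knee angle alone is ambiguous (the same angle occurs once
# during flexion and once during extension in every cycle) and the
# acceleration channels supply the disambiguating information.

feature_names <- c("kx", "ky", "hx", "hy", "a")

#' Labeled feature dataset
#'
#' Container for an n x 5 feature matrix with phase labels, plus optional
#' cycle / phase-segment bookkeeping and standardization parameters.
#'
#' @param x numeric matrix (n x 5), columns `kx, ky, hx, hy, a`
#' @param y integer phase labels in {1, 2, 3, 4}
#' @param cycle optional integer cycle index per row
#' @param segment optional integer phase-segment ("group") index per row
#' @param center,scale optional per-feature standardization parameters
#' @return object of class `labeled_dataset`
#' @export
labeled_dataset <- function(x, y, cycle = NULL, segment = NULL,
                            center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != 5) stop("feature matrix must have exactly five columns")
  colnames(x) <- feature_names
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("row counts of features and labels differ")
  if (!all(y %in% 1:4)) stop("labels must be in {1, 2, 3, 4}")
  structure(list(x = x, y = y, cycle = cycle, segment = segment,
                 center = center, scale = scale),
            class = "labeled_dataset")
}

#' Extract per-sample features from a recording
#'
#' One feature row `(kx, ky, hx, hy, a)` per sample; labels copied from the
#' recording. Cycle indices are recovered from the label sequence (a new
#' cycle starts where the label returns from upper buffer to pedaling) and
#' phase segments (one contiguous run of a single label -- the "groups" of
#' the group-level evaluation) are numbered consecutively.
#'
#' @param rec a labeled `cycling_recording`
#' @return a [labeled_dataset()]
#' @export
extract_features <- function(rec) {
  miss <- setdiff(c(feature_names, "label"), names(rec))
  if (length(miss)) stop("recording is missing column(s): ", paste(miss, collapse = ", "))
  lab <- as.integer(rec$label)
  if (any(is.na(lab))) stop("recording must be fully labeled")
  n <- length(lab)
  new_cycle <- c(TRUE, lab[-1] == 1L & lab[-n] == 4L)
  segment <- cumsum(c(TRUE, lab[-1] != lab[-n]))
  labeled_dataset(as.matrix(as.data.frame(rec)[feature_names]), lab,
                  cycle = cumsum(new_cycle), segment = segment)
}

#' Standardize features
#'
#' Per-feature zero mean, unit variance. Zero-variance features get scale 1
#' (mapping the column to zeros). Parameters are stored in the dataset and
#' reusable on test data via [apply_standardization()]; [destandardize()]
#' inverts the transform.
#'
#' @param ds a [labeled_dataset()]
#' @return the dataset with standardized features and stored parameters
#' @export
standardize <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (nrow(ds$x) < 1) stop("empty dataset")
  center <- colMeans(ds$x)
  scale <- apply(ds$x, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  ds$x <- sweep(sweep(ds$x, 2, center), 2, scale, "/")
  ds$center <- center
  ds$scale <- scale
  ds
}

#' @rdname standardize
#' @param params a standardized dataset (or list with `center` and `scale`)
#'   whose parameters are applied; test data never contributes statistics
#' @export
apply_standardization <- function(ds, params) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(params$center) || is.null(params$scale))
    stop("params must carry center and scale")
  ds$x <- sweep(sweep(ds$x, 2, params$center), 2, params$scale, "/")
  ds$center <- params$center
  ds$scale <- params$scale
  ds
}

#' @rdname standardize
#' @export
destandardize <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(ds$center)) stop("dataset carries no standardization parameters")
  ds$x <- sweep(sweep(ds$x, 2, ds$scale, "*"), 2, ds$center, "+")
  ds$center <- NULL
  ds$scale <- NULL
  ds
}

#' Group representatives: one median feature vector per phase segment
#'
#' A "group" is one contiguous phase segment of one cycle (50 cycles x 4
#' phases = 200 groups); its representative feature vector is the
#' per-feature median over the segment's samples.
#'
#' @param ds a [labeled_dataset()] with segment bookkeeping
#' @return a [labeled_dataset()] with one row per group
#' @export
group_medians <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(ds$segment)) stop("dataset carries no segment bookkeeping")
  segs <- unique(ds$segment)
  xg <- matrix(NA_real_, length(segs), 5, dimnames = list(NULL, feature_names))
  yg <- integer(length(segs))
  cg <- integer(length(segs))
  for (i in seq_along(segs)) {
    idx <- which(ds$segment == segs[i])
    xg[i, ] <- apply(ds$x[idx, , drop = FALSE], 2, median)
    yg[i] <- ds$y[idx[1]]
    cg[i] <- ds$cycle[idx[1]]
  }
  labeled_dataset(xg, yg, cycle = cg, segment = segs,
                  center = ds$center, scale = ds$scale)
}

#' Split a dataset at cycle granularity
#'
#' Cycles are sampled without replacement so that no sample (or group) of
#' one cycle appears in both sets; deterministic under `seed`.
#'
#' @param ds a [labeled_dataset()] with cycle bookkeeping
#' @param n_train_cycles,n_test_cycles cycle counts for the two sets
#' @param seed integer RNG seed
#' @return list with elements `train` and `test` ([labeled_dataset()]s) and
#'   the drawn `train_cycles` / `test_cycles`
#' @export
split_cycles <- function(ds, n_train_cycles, n_test_cycles, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(ds$cycle)) stop("dataset carries no cycle bookkeeping")
  cycles <- unique(ds$cycle)
  if (length(cycles) < n_train_cycles + n_test_cycles)
    stop("insufficient cycles: have ", length(cycles), ", need ",
         n_train_cycles + n_test_cycles)
  drawn <- with_seed(seed, sample(cycles, n_train_cycles + n_test_cycles))
  tr_cyc <- sort(drawn[seq_len(n_train_cycles)])
  te_cyc <- sort(drawn[n_train_cycles + seq_len(n_test_cycles)])
  subset_ds <- function(keep) {
    labeled_dataset(ds$x[keep, , drop = FALSE], ds$y[keep],
                    cycle = ds$cycle[keep], segment = ds$segment[keep],
                    center = ds$center, scale = ds$scale)
  }
  list(train = subset_ds(ds$cycle %in% tr_cyc),
       test = subset_ds(ds$cycle %in% te_cyc),
       train_cycles = tr_cyc, test_cycles = te_cyc)
}

#' Write / read a labeled dataset as CSV
#'
#' Columns `kx,ky,hx,hy,a,label` (plus `cycle`/`segment` when present).
#'
#' @param ds a [labeled_dataset()]
#' @param path file path
#' @return `read_dataset` returns a [labeled_dataset()]
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds$x)
  df$label <- ds$y
  if (!is.null(ds$cycle)) df$cycle <- ds$cycle
  if (!is.null(ds$segment)) df$segment <- ds$segment
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path)
  if (!all(c(feature_names, "label") %in% names(df)))
    stop("dataset CSV must have columns kx,ky,hx,hy,a,label")
  labeled_dataset(as.matrix(df[feature_names]), df$label,
                  cycle = df$cycle, segment = df$segment)
}
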