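#' Log2-transform a raw intensity matrix
#'
#' @param x An [expr_matrix()] of raw (linear-scale) intensities.
#' @param offset Non-negative pseudo-intensity added before the log; with
#'   the default 0 every value must be strictly positive.
#' @return The matrix with each value replaced by `log2(value + offset)`.
#' @export
log2_transform <- function(x, offset = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  if (offset < 0) stop("`offset` must be non-negative", call. = FALSE)
  bad <- which(x$values + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive value for probe '", rownames(x$values)[bad[1, 1]],
         "' (sample '", colnames(x$values)[bad[1, 2]],
         "'); use a positive `offset`", call. = FALSE)
  expr_matrix(log2(x$values + offset), x$sample_class)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the identical distribution: the
#' reference is the vector of row means of the column-sorted matrix, and
#' each column's values are replaced by the reference values at their
#' within-column ranks. Tied values in a column all receive the mean of
#' the reference values their rank span covers, so the map is
#' deterministic and the within-column ordering is preserved. The
#' operation is idempotent.
#'
#' @param x An [expr_matrix()] (log2 scale, >= 2 samples, no missing
#'   values).
#' @return The normalized [expr_matrix()]; after the call,
#'   `sort(column_i)` is identical across `i` up to tie averaging.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (ncol(v) < 2L)
    stop("quantile normalization needs >= 2 samples", call. = FALSE)
  if (anyNA(v)) stop("missing values in expression matrix", call. = FALSE)
  ref <- rowMeans(apply(v, 2, sort))
  # cumulative means of the sorted reference let a tie spanning ranks
  # [a, b] be assigned mean(ref[a:b]) in O(1)
  csum <- cumsum(ref)
  span_mean <- function(a, b) (csum[b] - if (a > 1) csum[a - 1] else 0) /
    (b - a + 1)
  out <- apply(v, 2, function(col) {
    o <- order(col)
    sorted <- col[o]
    res <- numeric(length(col))
    i <- 1L
    while (i <= length(col)) {
      j <- i
      while (j < length(col) && sorted[j + 1L] == sorted[i]) j <- j + 1L
      res[o[i:j]] <- span_mean(i, j)
      i <- j + 1L
    }
    res
  })
  dimnames(out) <- dimnames(v)
  expr_matrix(out, x$sample_class)
}

#' Filter probes by signal-to-noise ratio
#'
#' Keeps exactly the genes whose probe satisfies `signal / noise >
#' threshold` (strict inequality; a probe at SNR = 2 is dropped at the
#' default). Row order of survivors is preserved.
#'
#' @param x An [expr_matrix()].
#' @param probes Data frame with columns `probe_id`, `signal`, `noise`
#'   covering every gene of `x` (one row per gene).
#' @param threshold SNR threshold, default 2.
#' @return The filtered [expr_matrix()].
#' @export
snr_filter <- function(x, probes, threshold = 2) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!all(c("probe_id", "signal", "noise") %in% names(probes)))
    stop("`probes` needs columns probe_id, signal, noise", call. = FALSE)
  idx <- match(rownames(x$values), probes$probe_id)
  if (anyNA(idx))
    stop("no probe record for gene '",
         rownames(x$values)[which(is.na(idx))[1]], "'", call. = FALSE)
  if (any(probes$noise[idx] <= 0))
    stop("probe noise must be > 0", call. = FALSE)
  keep <- probes$signal[idx] / probes$noise[idx] > threshold
  subset_expr(x, genes = rownames(x$values)[keep])
}

#' Standard preprocessing chain
#'
#' Applies the probe filter and normalization in the conventional order:
#' SNR filter first (so unexpressed probes do not distort the reference
#' distribution), then log2 transform, then quantile normalization. The
#' order of filter vs. normalization is configurable.
#'
#' @param x Raw-intensity [expr_matrix()].
#' @param probes Optional probe table for [snr_filter()]; `NULL` skips the
#'   filter.
#' @param snr_threshold SNR threshold, default 2.
#' @param offset Offset for [log2_transform()].
#' @param filter_first If `FALSE`, normalize before filtering.
#' @return Preprocessed [expr_matrix()] on the log2 scale.
#' @export
preprocess <- function(x, probes = NULL, snr_threshold = 2, offset = 0,
                       filter_first = TRUE) {
  if (filter_first && !is.null(probes))
    x <- snr_filter(x, probes, snr_threshold)
  x <- quantile_normalize(log2_transform(x, offset))
  if (!filter_first && !is.null(probes))
    x <- snr_filter(x, probes, snr_threshold)
  x
}
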