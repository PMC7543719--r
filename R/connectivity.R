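#' Sliding-window specification
#'
#' Window length and step are fixed in samples: `win = round(window_seconds *
#' fs)` and `step = round(win * (1 - overlap_fraction))`. The defaults encode
#' the 2-second window with 50% overlap used throughout the analysis.
#'
#' @param window_seconds Window length in seconds (default 2).
#' @param overlap_fraction Overlap in `[0, 1)` (default 0.5).
#' @param fs Sampling rate in Hz; always supplied, never inferred.
#' @return A `window_spec` list with `win` and `step` in samples.
#' @export
window_spec <- function(window_seconds = 2, overlap_fraction = 0.5, fs) {
  if (missing(fs) || !is.numeric(fs) || fs <= 0) stop("fs (Hz) must be supplied and > 0")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  win <- as.integer(round(window_seconds * fs))
  step <- as.integer(round(win * (1 - overlap_fraction)))
  if (win < 2L) stop("window length must be >= 2 samples")
  if (step < 1L) stop("window step must be >= 1 sample")
  structure(list(window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction, fs = fs,
                 win = win, step = step),
            class = "window_spec")
}

#' Enumerate full sliding windows
#'
#' Windows start at the first sample and advance by the spec's step; trailing
#' samples that cannot fill a complete window are dropped, so every
#' correlation estimate uses the same number of samples. The count is
#' `floor((n_samples - win) / step) + 1`.
#'
#' @param n_samples Number of samples available.
#' @param spec A [window_spec()].
#' @return data.frame with columns `start`, `end`: half-open intervals, the
#'   window covering samples `start .. end - 1` (1-based).
#' @export
make_windows <- function(n_samples, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (n_samples < spec$win)
    stop("n_samples (", n_samples, ") shorter than window length (", spec$win, ")")
  starts <- seq.int(1L, n_samples - spec$win + 1L, by = spec$step)
  data.frame(start = starts, end = starts + spec$win)
}

#' Randomly place recording epochs with a minimum separation
#'
#' Draws up to `n_epochs` non-overlapping epochs of `epoch_seconds` in
#' temporal order, with at least `min_gap_seconds` between the end of one and
#' the start of the next. If the recording cannot hold the requested number
#' at that spacing, as many epochs as fit are returned (at least one, else an
#' error). Placement is uniform: the feasible layouts form a simplex of start
#' offsets, sampled by sorting k iid uniform draws over the spare samples.
#' Deterministic given `seed`.
#'
#' @param n_samples Recording length in samples.
#' @param fs Sampling rate in Hz.
#' @param n_epochs Epochs requested (default 3).
#' @param epoch_seconds Epoch length in seconds (default 60).
#' @param min_gap_seconds Minimum separation in seconds (default 300).
#' @param seed Integer seed.
#' @return data.frame with columns `start`, `end` (half-open, 1-based), one
#'   row per epoch in temporal order.
#' @export
select_epochs <- function(n_samples, fs, n_epochs = 3, epoch_seconds = 60,
                          min_gap_seconds = 300, seed) {
  ep <- as.integer(round(epoch_seconds * fs))
  gap <- as.integer(round(min_gap_seconds * fs))
  if (n_samples < ep)
    stop("recording (", n_samples, " samples) shorter than one epoch (", ep, ")")
  need <- function(k) k * ep + (k - 1L) * gap
  k <- as.integer(n_epochs)
  while (k > 1L && need(k) > n_samples) k <- k - 1L
  slack <- n_samples - need(k)
  offsets <- with_seed(seed, sort(sample.int(slack + 1L, k, replace = TRUE) - 1L))
  starts <- 1L + (seq_len(k) - 1L) * (ep + gap) + offsets
  data.frame(start = starts, end = starts + ep)
}

# Pearson correlation of rows over a sample range via one centered
# cross-product; identical to stats::cor of the transposed slice to machine
# precision but considerably faster on wide windows. Errors (naming regions)
# on zero variance, which signals flat/degenerate input.
.row_correlation <- function(x, cols) {
  Y <- x[, cols, drop = FALSE]
  Y <- Y - rowMeans(Y)
  S <- tcrossprod(Y)
  d <- sqrt(diag(S))
  if (any(d == 0)) {
    bad <- rownames(x)[d == 0]
    if (is.null(bad)) bad <- which(d == 0)
    stop("zero variance within window for region(s): ",
         paste(bad, collapse = ", "))
  }
  R <- S / tcrossprod(d)
  diag(R) <- 1
  R
}

#' Pearson correlation matrix of one window
#'
#' Amplitude correlation: plain Pearson correlation between all region pairs
#' over the samples of a single window.
#'
#' @param ts Matrix (regions x samples); rownames are region ids.
#' @param window Either a length-2 vector `c(start, end)` (half-open, 1-based)
#'   or a single row of [make_windows()].
#' @return Symmetric correlation matrix with unit diagonal (`kind` attribute
#'   `"window"`).
#' @export
window_correlation <- function(ts, window) {
  if (is.data.frame(window)) window <- c(window$start[1], window$end[1])
  start <- window[1]; end <- window[2]
  if (start < 1 || end > ncol(ts) + 1 || end - start < 2)
    stop("window [", start, ", ", end, ") outside time series bounds")
  R <- .row_correlation(ts, start:(end - 1))
  attr(R, "kind") <- "window"
  R
}

#' Temporal average of window connectivity matrices
#'
#' Element-wise arithmetic mean of raw correlation values (no
#' variance-stabilizing transform), yielding the single functional network of
#' an epoch.
#'
#' @param fcs Non-empty list of equally sized window correlation matrices.
#' @return Matrix of the same shape, `kind` attribute `"epoch_mean"`.
#' @export
average_epoch_fc <- function(fcs) {
  if (!is.list(fcs) || length(fcs) == 0L)
    stop("fcs must be a non-empty list of matrices")
  dims <- vapply(fcs, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all window matrices must have identical dimensions")
  ids <- lapply(fcs, rownames)
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("window matrices index different regions")
  M <- Reduce(`+`, fcs) / length(fcs)
  attr(M, "kind") <- "epoch_mean"
  M
}

#' Epoch-mean functional connectivity in one call
#'
#' Convenience composition of [make_windows()], [window_correlation()] and
#' [average_epoch_fc()] over a sample range; used by the cohort pipeline.
#'
#' @param ts Matrix (regions x samples).
#' @param spec A [window_spec()].
#' @param epoch Optional `c(start, end)` half-open range (default: all samples).
#' @return Epoch-mean correlation matrix.
#' @export
epoch_mean_fc <- function(ts, spec, epoch = NULL) {
  if (is.null(epoch)) epoch <- c(1L, ncol(ts) + 1L)
  seg <- ts[, epoch[1]:(epoch[2] - 1L), drop = FALSE]
  w <- make_windows(ncol(seg), spec)
  S <- 0
  for (i in seq_len(nrow(w)))
    S <- S + .row_correlation(seg, w$start[i]:(w$end[i] - 1L))
  M <- S / nrow(w)
  diag(M) <- 1
  attr(M, "kind") <- "epoch_mean"
  M
}

#' Mask inter-hemispheric connections
#'
#' Replaces entries linking regions of different hemispheres with `NA` so that
#' no downstream mean can silently include them; within-hemisphere entries and
#' the diagonal are unchanged. Idempotent.
#'
#' @param fc Square connectivity matrix in atlas order.
#' @param atlas A `region_atlas` with one row per matrix row.
#' @return The masked matrix.
#' @export
drop_interhemispheric <- function(fc, atlas) {
  validate_atlas(atlas)
  if (nrow(fc) != nrow(atlas) || ncol(fc) != nrow(atlas))
    stop("fc dimensions do not match atlas")
  same <- outer(atlas$hemisphere, atlas$hemisphere, "==")
  fc[!same] <- NA_real_
  fc
}
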