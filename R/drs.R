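#' Intra-hemispheric node strength
#'
#' Strength of region i is the mean Pearson correlation between i and every
#' other region of the same hemisphere; connections crossing the midline
#' never enter, whether or not the matrix has been masked with
#' [drop_interhemispheric()]. High-strength nodes are the network's hubs.
#'
#' @param fc Epoch-mean connectivity matrix in atlas order.
#' @param atlas A `region_atlas` (>= 2 regions per hemisphere).
#' @return Named numeric vector (names = region ids), one strength in
#'   `[-1, 1]` per region.
#' @export
intra_hemispheric_strength <- function(fc, atlas) {
  validate_atlas(atlas)
  n <- nrow(atlas)
  if (nrow(fc) != n || ncol(fc) != n) stop("fc dimensions do not match atlas")
  strength <- numeric(n)
  for (h in c("L", "R")) {
    idx <- which(atlas$hemisphere == h)
    if (length(idx) < 2L)
      stop("hemisphere ", h, " has fewer than 2 regions; strength undefined")
    block <- fc[idx, idx, drop = FALSE]
    diag(block) <- NA_real_
    strength[idx] <- rowMeans(block, na.rm = TRUE)
  }
  names(strength) <- atlas$region_id
  strength
}

#' D_RS from two strength samples
#'
#' The core rank statistic: the normalized Mann-Whitney U of the spared
#' sample over all removed x spared pairs, with half credit for ties,
#' `D_RS = [#(spared > removed) + 0.5 #(ties)] / (n_removed * n_spared)`.
#' 0 means every removed node is stronger than every spared node (the
#' resection captured the hubs); 1 the reverse; 0.5 indistinguishable.
#' Computed via midranks, which is algebraically identical to exhaustive pair
#' counting.
#'
#' @param removed_strengths,spared_strengths Non-empty numeric vectors.
#' @return D_RS in `[0, 1]`.
#' @export
drs_from_strengths <- function(removed_strengths, spared_strengths) {
  nr <- length(removed_strengths); ns <- length(spared_strengths)
  if (nr == 0L || ns == 0L)
    stop("need at least one removed and one spared strength")
  if (anyNA(removed_strengths) || anyNA(spared_strengths))
    stop("strengths must not contain NA")
  r <- rank(c(spared_strengths, removed_strengths))
  u_spared <- sum(r[seq_len(ns)]) - ns * (ns + 1) / 2
  u_spared / (nr * ns)
}

#' D_RS: distinguishability of removed vs spared node strength
#'
#' Applies [drs_from_strengths()] to a strength vector under a removed/spared
#' partition. By default the spared side comprises all non-removed regions of
#' both hemispheres (each node's strength is still intra-hemispheric);
#' `spared_scope = "ipsilateral"` restricts it to the resected hemisphere.
#'
#' @param strength Named strength vector from [intra_hemispheric_strength()].
#' @param labels A `removal_labels` object (or a vector of removed region ids).
#' @param atlas A `region_atlas`; required for `spared_scope = "ipsilateral"`.
#' @param spared_scope `"both"` (default) or `"ipsilateral"`.
#' @param subject_id,epoch_index Optional identifiers carried into the result.
#' @return A `drs_result` list: `drs`, `n_removed`, `n_spared`,
#'   `spared_scope`, plus any identifiers.
#' @export
drs_statistic <- function(strength, labels, atlas = NULL,
                          spared_scope = c("both", "ipsilateral"),
                          subject_id = NA_character_, epoch_index = NA_integer_) {
  spared_scope <- match.arg(spared_scope)
  if (inherits(labels, "removal_labels")) {
    removed <- labels$removed
  } else {
    removed <- unique(as.integer(labels))
  }
  ids <- as.integer(names(strength))
  if (anyNA(ids)) stop("strength vector must be named by region id")
  if (length(removed) == 0L) stop("removed set is empty; D_RS undefined")
  if (!all(removed %in% ids))
    stop("removed region(s) absent from strength vector: ",
         paste(setdiff(removed, ids), collapse = ", "))
  spared <- setdiff(ids, removed)
  if (spared_scope == "ipsilateral") {
    if (is.null(atlas)) stop("atlas required for spared_scope = 'ipsilateral'")
    validate_atlas(atlas)
    hemis <- unique(atlas$hemisphere[match(removed, atlas$region_id)])
    if (length(hemis) != 1L)
      stop("removed regions span both hemispheres; ipsilateral scope undefined")
    spared <- intersect(spared, atlas$region_id[atlas$hemisphere == hemis])
  }
  if (length(spared) == 0L) stop("spared set is empty; D_RS undefined")
  structure(list(
    drs = drs_from_strengths(strength[as.character(removed)],
                             strength[as.character(spared)]),
    n_removed = length(removed),
    n_spared = length(spared),
    spared_scope = spared_scope,
    subject_id = subject_id,
    epoch_index = epoch_index
  ), class = "drs_result")
}

#' @export
print.drs_result <- function(x, ...) {
  cat(sprintf("D_RS = %.4f (removed %d, spared %d, scope %s)\n",
              x$drs, x$n_removed, x$n_spared, x$spared_scope))
  invisible(x)
}
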