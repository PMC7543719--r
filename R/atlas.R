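#' Build a two-hemisphere region atlas
#'
#' Creates the canonical ordered region table used throughout the package:
#' `region_id` 1..n, the first half labeled hemisphere `"L"`, the second half
#' `"R"`. Every matrix and vector downstream indexes regions in this order.
#'
#' @param n_regions Even integer >= 4; total number of cortical regions.
#'   The multi-resolution parcellations this emulates come in scales of
#'   68/114/219/448 regions, but any even count >= 4 is accepted.
#' @return A `region_atlas`: a data.frame with columns `region_id` (integer),
#'   `name` (character) and `hemisphere` (`"L"` or `"R"`).
#' @examples
#' atlas <- build_atlas(114)
#' table(atlas$hemisphere)
#' @export
build_atlas <- function(n_regions) {
  if (length(n_regions) != 1L || !is.finite(n_regions) ||
      n_regions != as.integer(n_regions))
    stop("n_regions must be a single integer")
  n_regions <- as.integer(n_regions)
  if (n_regions < 4L) stop("n_regions must be >= 4 (need >= 2 regions per hemisphere)")
  if (n_regions %% 2L != 0L) stop("n_regions must be even (equal hemispheres)")
  half <- n_regions %/% 2L
  hemisphere <- rep(c("L", "R"), each = half)
  atlas <- data.frame(
    region_id = seq_len(n_regions),
    name = sprintf("%s_roi_%03d", hemisphere, c(seq_len(half), seq_len(half))),
    hemisphere = hemisphere,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

validate_atlas <- function(atlas) {
  if (!is.data.frame(atlas) ||
      !all(c("region_id", "name", "hemisphere") %in% names(atlas)))
    stop("atlas must have columns region_id, name, hemisphere")
  if (anyDuplicated(atlas$region_id)) stop("atlas region_id values must be unique")
  if (!all(atlas$hemisphere %in% c("L", "R")))
    stop("atlas hemisphere must be 'L' or 'R'")
  if (any(table(factor(atlas$hemisphere, levels = c("L", "R"))) < 2L))
    stop("atlas needs at least 2 regions per hemisphere")
  invisible(atlas)
}

# Integer indices (in atlas order) of each hemisphere.
hemisphere_index <- function(atlas) {
  split(seq_len(nrow(atlas)), atlas$hemisphere)
}

#' Read / write an atlas table
#'
#' Tab-separated with a header line: `region_id`, `name`, `hemisphere`.
#'
#' @param path File path.
#' @return `read_atlas` returns a `region_atlas`; `write_atlas` returns
#'   `path` invisibly.
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  atlas$region_id <- as.integer(atlas$region_id)
  class(atlas) <- c("region_atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

#' @rdname read_atlas
#' @param atlas A `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
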