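#' Removed/spared labels from an explicit region list
#'
#' The list-input path for subjects whose resection is known from a surgery
#' report rather than imaging.
#'
#' @param removed_ids Non-empty set of region ids.
#' @param atlas A `region_atlas`.
#' @return A `removal_labels` list with integer vectors `removed` and
#'   `spared` partitioning the atlas.
#' @export
label_from_list <- function(removed_ids, atlas) {
  validate_atlas(atlas)
  removed_ids <- unique(as.integer(removed_ids))
  if (length(removed_ids) == 0L) stop("removed_ids must be nonempty")
  unknown <- setdiff(removed_ids, atlas$region_id)
  if (length(unknown))
    stop("region id(s) not in atlas: ", paste(unknown, collapse = ", "))
  structure(list(removed = sort(removed_ids),
                 spared = sort(setdiff(atlas$region_id, removed_ids))),
            class = "removal_labels")
}

#' Removed/spared labels from parcellation and resection-mask volumes
#'
#' Applies the any-overlap rule: a region is labeled removed if at least one
#' voxel carries its parcellation label and lies under the binary resection
#' mask; every other atlas region is spared. Both volumes must already be on
#' the same grid (registration is upstream of this package). Background
#' voxels (label 0) are ignored; label ids absent from the atlas are an error
#' to guard against mismatched parcellation scales.
#'
#' @param labels Integer 3-D array of per-voxel region ids (0 = background).
#' @param mask Binary 3-D array of the same shape (1 = resected tissue).
#' @param atlas A `region_atlas`.
#' @return A `removal_labels` list (`removed` may be empty, with a warning,
#'   if the mask touches no labeled voxel).
#' @export
label_from_volumes <- function(labels, mask, atlas) {
  validate_atlas(atlas)
  if (!identical(dim(labels), dim(mask)))
    stop("labels and mask grids differ: ",
         paste(dim(labels), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"))
  mv <- unique(as.vector(mask))
  if (!all(mv %in% c(0, 1)))
    stop("mask must be binary (values 0/1); found: ",
         paste(setdiff(mv, c(0, 1)), collapse = ", "))
  present <- setdiff(unique(as.integer(labels)), 0L)
  unknown <- setdiff(present, atlas$region_id)
  if (length(unknown))
    stop("label volume contains region id(s) not in atlas: ",
         paste(unknown, collapse = ", "))
  removed <- sort(setdiff(unique(as.integer(labels[mask == 1])), 0L))
  if (length(removed) == 0L)
    warning("resection mask overlaps no labeled region: empty removed set")
  structure(list(removed = removed,
                 spared = sort(setdiff(atlas$region_id, removed))),
            class = "removal_labels")
}

#' Removed/spared labels from NIfTI volumes on disk
#'
#' Reads a parcellation label volume and a binary resection mask (`.nii` /
#' `.nii.gz`) and applies [label_from_volumes()].
#'
#' @param parcellation_path,mask_path NIfTI file paths (same grid).
#' @param atlas A `region_atlas`.
#' @return A `removal_labels` list.
#' @export
label_from_nifti <- function(parcellation_path, mask_path, atlas) {
  labels <- round(as.array(RNifti::readNifti(parcellation_path)))
  mask <- as.array(RNifti::readNifti(mask_path))
  storage.mode(labels) <- "integer"
  label_from_volumes(labels, mask, atlas)
}

#' @export
print.removal_labels <- function(x, ...) {
  cat(sprintf("removal labels: %d removed, %d spared\n",
              length(x$removed), length(x$spared)))
  invisible(x)
}
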