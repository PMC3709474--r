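#' Erode a binary mask by one voxel layer
#'
#' Removes every voxel that has at least one face neighbour (6-connectivity
#' by default) outside the mask, i.e. peels off the outer layer. Used by
#' the control analysis that re-runs decoding on eroded regions to exclude
#' contributions from voxels bordering neighbouring areas. 26-connectivity
#' (faces, edges and corners) is available behind the `connectivity` flag.
#'
#' @param mask binary 3D array.
#' @param connectivity 6 (face neighbours, default) or 26.
#' @return eroded binary mask, a subset of the input; error if empty.
#' @export
erode_mask <- function(mask, connectivity = 6) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 26))
  if (!any(mask != 0)) stop("mask is empty")
  d <- dim(mask)
  # pad with zeros so voxels on the grid boundary count as having an
  # outside neighbour
  p <- array(0L, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.integer(mask != 0)
  shifts <- if (connectivity == 6) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- expand.grid(-1:1, -1:1, -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  core <- p
  for (s in shifts) {
    shifted <- p[(2:(d[1] + 1)) - s[1], (2:(d[2] + 1)) - s[2],
                 (2:(d[3] + 1)) - s[3], drop = FALSE]
    core[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
      core[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] * shifted
  }
  out <- core[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  dim(out) <- d
  if (!any(out != 0))
    stop("erosion left no voxels; use a larger ROI")
  out
}

#' Regions of interest from an integer parcellation volume
#'
#' Splits a labelled volume (one integer label per parcel, 0 = background)
#' into one binary mask per label, keeping parcels with at least
#' `min_voxels` voxels; smaller parcels are reported and skipped. This is
#' the generic machinery behind whole-brain parcellation control analyses.
#'
#' @param parcellation integer 3D array on the functional grid.
#' @param min_voxels minimum parcel size to keep.
#' @param names optional named character vector mapping label to name.
#' @return named list of binary masks (names `label_<l>` unless supplied).
#' @export
parcellation_rois <- function(parcellation, min_voxels = 2, names = NULL) {
  stopifnot(length(dim(parcellation)) == 3)
  tab <- table(parcellation[parcellation != 0])
  if (length(tab) == 0) stop("parcellation volume contains no non-zero labels")
  keep <- names(tab)[tab >= min_voxels]
  small <- names(tab)[tab < min_voxels]
  if (length(small))
    message(sprintf("skipping %d parcel(s) below %d voxels: %s",
                    length(small), min_voxels, paste(small, collapse = ", ")))
  if (length(keep) == 0)
    stop(sprintf("no parcel has at least %d voxels", min_voxels))
  rois <- lapply(keep, function(l) {
    m <- array(0L, dim(parcellation))
    m[parcellation == as.numeric(l)] <- 1L
    m
  })
  nm <- if (!is.null(names)) unname(names[keep]) else paste0("label_", keep)
  stats::setNames(rois, nm)
}

#' Split a mask at a sagittal plane
#'
#' Utility for per-hemisphere analyses: splits a mask into the part with
#' x below the plane and the part at or above it (default: the grid's
#' x midline).
#'
#' @param mask binary 3D array.
#' @param plane x index of the splitting plane (first voxel of the "right"
#'   half); default `dim(mask)[1] / 2 + 1`.
#' @return list with masks `left` and `right`.
#' @export
split_hemispheres <- function(mask, plane = NULL) {
  stopifnot(length(dim(mask)) == 3)
  d <- dim(mask)
  if (is.null(plane)) plane <- floor(d[1] / 2) + 1
  left <- mask; left[plane:d[1], , ] <- 0L
  right <- mask; right[1:(plane - 1), , ] <- 0L
  list(left = left, right = right)
}

#' Read an integer parcellation volume from NIfTI
#'
#' @param path NIfTI file with integer labels.
#' @return 3D integer array.
#' @export
read_parcellation <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.integer(round(img)), dim(img))
}
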