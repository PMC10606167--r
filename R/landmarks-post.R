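# Deterministic post-processing of predicted landmark mask volumes into
# world-coordinate landmarks: binarize at a threshold, keep the largest
# 26-connected component, take the voxel centroid, and map it through the
# voxel-to-world affine into LPS mm.

#' Construct a landmark mask volume
#'
#' A 5-channel scalar volume (one channel per landmark, values in [0, 1])
#' with a voxel-index-to-world affine. Voxel indices are 0-based, matching
#' the NIfTI convention.
#'
#' @param values 4D array `(x, y, z, channel)` with 5 channels, finite
#'   values in `[0, 1]`.
#' @param affine 4 x 4 invertible voxel-to-world (LPS mm) matrix.
#' @return Object of class `landmark_mask_volume`.
#' @export
landmark_mask_volume <- function(values, affine) {
  values <- as.array(values)
  if (length(dim(values)) != 4 || dim(values)[4] != 5) {
    stop("landmark mask volume must be 4D with exactly 5 channels", call. = FALSE)
  }
  if (!all(is.finite(values)) || min(values) < 0 || max(values) > 1) {
    stop("landmark mask values must be finite in [0, 1]", call. = FALSE)
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12) {
    stop("affine must be an invertible 4 x 4 matrix", call. = FALSE)
  }
  structure(list(values = values, affine = affine),
            class = "landmark_mask_volume")
}

# 26-connected components of a logical 3D mask; returns the voxel index
# matrix (1-based, n x 3) of the largest component. Ties break toward the
# component containing the lexicographically smallest voxel index.
largest_component_voxels <- function(mask) {
  dm <- dim(mask)
  vox <- which(mask)
  if (length(vox) == 0) return(NULL)
  coord <- arrayInd(vox, dm)
  # neighbor offsets (26-connectivity) on the flattened index grid
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  lin <- function(co) (co[, 3] - 1) * dm[1] * dm[2] + (co[, 2] - 1) * dm[1] + co[, 1]
  vox_lin <- lin(coord)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coord, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    hit <- match(lin(nb[ok, , drop = FALSE]), vox_lin)
    sel <- !is.na(hit)
    from <- c(from, which(ok)[sel])
    to <- c(to, hit[sel])
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(from) > 0) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie: component whose minimum linear voxel index is smallest
    first_lin <- vapply(best, function(ci) {
      min(vox_lin[comp$membership == ci])
    }, 0)
    best <- best[which.min(first_lin)]
  }
  coord[comp$membership == best[1], , drop = FALSE]
}

#' Extract a world-coordinate landmark from one mask channel
#'
#' Binarizes the channel at `threshold`, keeps the largest 26-connected
#' component, computes the (unweighted) centroid of its voxel indices, and
#' maps it through the affine to world LPS mm. Returns `NULL` (absent, not
#' an error) when no voxel exceeds the threshold.
#'
#' @param channel 3D scalar array.
#' @param affine 4 x 4 voxel(0-based)-to-world matrix.
#' @param threshold Binarization threshold, default 0.5.
#' @return Length-3 world point (mm), or `NULL` when the channel is empty.
#' @export
mask_to_landmark <- function(channel, affine, threshold = 0.5) {
  affine <- as.matrix(affine)
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible", call. = FALSE)
  voxels <- largest_component_voxels(channel > threshold)
  if (is.null(voxels)) return(NULL)
  cen0 <- colMeans(voxels) - 1           # 0-based voxel centroid
  as.numeric((affine %*% c(cen0, 1))[1:3])
}

#' Landmark set from a 5-channel mask volume
#'
#' Applies [mask_to_landmark()] to every channel, binding channels to
#' landmark names through `channel_map`. A missing landmark (empty channel)
#' is an error naming the landmark.
#'
#' @param vol A [landmark_mask_volume()] (or 4D array plus `affine`).
#' @param channel_map Named integer vector mapping each of the five landmark
#'   names to a channel index (a bijection onto 1..5). Default: channels in
#'   the order left/right coronary ostium, LC/RC/NC nadir.
#' @param affine Affine override when `vol` is a plain array.
#' @param threshold Binarization threshold.
#' @return A [landmark_set()].
#' @export
masks_to_landmark_set <- function(vol,
                                  channel_map = stats::setNames(1:5, LANDMARK_NAMES),
                                  affine = NULL, threshold = 0.5) {
  if (!inherits(vol, "landmark_mask_volume")) {
    vol <- landmark_mask_volume(vol, affine)
  }
  if (!setequal(names(channel_map), LANDMARK_NAMES) ||
      !setequal(channel_map, 1:5)) {
    stop("channel_map must map the 5 landmark names bijectively onto channels 1..5",
         call. = FALSE)
  }
  pts <- lapply(LANDMARK_NAMES, function(nm) {
    mask_to_landmark(vol$values[, , , channel_map[[nm]]], vol$affine, threshold)
  })
  names(pts) <- LANDMARK_NAMES
  absent <- names(pts)[vapply(pts, is.null, TRUE)]
  if (length(absent) > 0) {
    stop("missing landmark(s): ", paste(absent, collapse = ", "),
         " (no voxel above threshold ", threshold, ")", call. = FALSE)
  }
  do.call(landmark_set, pts)
}

#' Read a landmark mask volume from a NIfTI file
#'
#' Reads a 4D (5-channel) NIfTI volume; the voxel-to-world affine is taken
#' from the header as stored and interpreted in LPS mm, consistent with the
#' package-wide frame convention (no axis flipping is applied).
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A [landmark_mask_volume()].
#' @export
read_landmark_mask <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  landmark_mask_volume(as.array(img), as.matrix(aff))
}
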