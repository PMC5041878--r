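#' Fill enclosed cavities of a binary tumor mask
#'
#' Contrast-enhancing tumor segmentations are rims around a necrotic core;
#' the analysis works on solid volumes, so any cavity fully enclosed by the
#' mask is filled. A cavity is a background component (6-connectivity) that
#' does not reach the array boundary: the output is the complement of the
#' boundary-connected background. Background uses 6-connectivity (the
#' complementary convention to 26-connected foreground) so diagonal contact
#' between a cavity and the outside does not count as a leak.
#'
#' The operation is idempotent and never removes voxels.
#'
#' @param mask Nonempty binary 3-D array.
#' @return Logical array of the same shape with cavities filled.
#' @examples
#' shell <- array(TRUE, c(5, 5, 5)); shell[2:4, 2:4, 2:4] <- FALSE
#' shell[3, 3, 3] <- FALSE # hollow cube
#' sum(fill_ce_volume(shell)) # 125
#' @export
fill_ce_volume <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stopf("cannot fill an empty mask")
  bg <- !mask
  d <- dim(mask)
  # Seed the flood fill with all background voxels on the array boundary.
  reach <- array(FALSE, d)
  reach[c(1L, d[1]), , ] <- TRUE
  reach[, c(1L, d[2]), ] <- TRUE
  reach[, , c(1L, d[3])] <- TRUE
  reach <- reach & bg
  repeat {
    grown <- reach
    for (axis in 1:3) {
      grown <- (grown | shift_mask(grown, axis, 1L) |
                  shift_mask(grown, axis, -1L)) & bg
    }
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  !reach
}

#' Label 26-connected components of a binary mask
#'
#' @param mask Logical 3-D array.
#' @return Integer array of the same shape: 0 for background, 1..n for
#'   components labelled in first-encounter (column-major) order.
#' @keywords internal
label_components <- function(mask) {
  mask <- as_mask(mask)
  d <- dim(mask)
  labels <- array(0L, d)
  todo <- which(mask)
  if (length(todo) == 0L) return(labels)
  inside <- array(FALSE, d)
  inside[todo] <- TRUE
  # 26-neighbourhood index offsets, valid only away from grid faces;
  # frontier voxels on a face are expanded coordinate-wise instead.
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  lab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier)) {
      ijk <- arrayInd(frontier, d)
      nb <- ijk[rep(seq_len(nrow(ijk)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(ijk)), , drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
        nb[, 2] >= 1L & nb[, 2] <= d[2] &
        nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L))
      lin <- lin[inside[lin] & labels[lin] == 0L]
      labels[lin] <- lab
      frontier <- lin
    }
  }
  labels
}

#' Centre of mass of a binary mask in world coordinates
#'
#' Unweighted mean of the world-coordinate centres of all foreground voxels,
#' computed on the (filled) mask. Because the affine is linear, this equals
#' the affine image of the mean voxel index.
#'
#' @param mask Nonempty binary 3-D array on the template grid.
#' @param template A [template_space()].
#' @return Numeric length-3 world point (mm), named `x`, `y`, `z`.
#' @export
centroid <- function(mask, template) {
  mask <- as_mask(mask)
  if (!any(mask)) stopf("cannot take the centroid of an empty mask")
  if (!all(dim(mask) == template$shape)) {
    stopf("mask shape does not match the template grid")
  }
  ijk <- arrayInd(which(mask), dim(mask)) - 1 # 0-based
  w <- voxel_to_world(colMeans(ijk), template)
  stats::setNames(as.numeric(w), c("x", "y", "z"))
}

#' Rasterize a sphere around a world point
#'
#' Mask of all voxels whose world-coordinate centres lie within `radius_mm`
#' of `center` (closed ball), clipped to the grid. The 15 mm default is the
#' radius used for centroid density maps.
#'
#' @param center Numeric length-3 world point (mm).
#' @param radius_mm Positive radius in mm.
#' @param template A [template_space()].
#' @return Logical array of the grid shape.
#' @export
centroid_sphere <- function(center, radius_mm = 15, template) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stopf("center must be a finite world point")
  }
  if (!is.finite(radius_mm) || radius_mm <= 0) stopf("radius_mm must be > 0")
  d <- template$shape
  # Bounding box in voxel space: project the ball's world bounding box
  # through the inverse affine corner-wise.
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * radius_mm
  corners <- sweep(corners, 2, center, `+`)
  vox <- world_to_voxel(corners, template)
  lo <- pmax(floor(apply(vox, 2, min)), 0)
  hi <- pmin(ceiling(apply(vox, 2, max)), d - 1)
  if (any(lo > hi)) {
    stopf("sphere at (%s), radius %g mm lies entirely outside the grid",
          paste(format(center), collapse = ", "), radius_mm)
  }
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  w <- voxel_to_world(box, template)
  inside <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 +
    (w[, 3] - center[3])^2 <= radius_mm^2
  out <- array(FALSE, d)
  out[box[inside, , drop = FALSE] + 1L] <- TRUE
  out
}
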