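#' Template space: the shared coordinate frame for all subjects
#'
#' A `template_space` bundles the grid geometry and the two reference masks
#' every stage of the pipeline needs: grid shape, voxel spacing in mm, a 4x4
#' voxel-to-world affine (0-based voxel indices, NIfTI sform convention),
#' a brain mask and a lateral-ventricle mask on the same grid. A real
#' template (e.g. MNI152 with a ventricle atlas) can be loaded into this
#' structure with [read_template()]; [make_template()] builds a synthetic
#' stand-in.
#'
#' @param shape Integer length-3 grid dimensions (voxels).
#' @param spacing Positive numeric length-3 voxel spacing (mm).
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal affine
#'   placing the world origin at the grid centre, so the mid-sagittal plane
#'   is `x = 0` and negative world x is the left hemisphere.
#' @param brain_mask,ventricle_mask Logical 3-D arrays on the grid.
#' @return An object of class `template_space`.
#' @export
template_space <- function(shape, spacing, affine = NULL,
                           brain_mask, ventricle_mask) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape < 1L)) {
    stopf("shape must be three positive integers")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("spacing components must be strictly positive")
  }
  if (is.null(affine)) {
    centre <- (shape - 1) / 2
    affine <- rbind(cbind(diag(spacing), -spacing * centre), c(0, 0, 0, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) {
    stopf("affine must be an invertible 4x4 matrix")
  }
  brain_mask <- as_mask(brain_mask, "brain_mask")
  ventricle_mask <- as_mask(ventricle_mask, "ventricle_mask")
  if (!all(dim(brain_mask) == shape) || !all(dim(ventricle_mask) == shape)) {
    stopf("masks must match the grid shape (%s)", paste(shape, collapse = "x"))
  }
  if (!any(brain_mask)) stopf("brain_mask is empty")
  if (!any(ventricle_mask)) stopf("ventricle_mask is empty")
  if (any(ventricle_mask & !brain_mask)) {
    stopf("invariant violated: every ventricle voxel must lie in the brain mask")
  }
  structure(
    list(shape = shape, spacing = spacing, affine = affine,
         brain_mask = brain_mask, ventricle_mask = ventricle_mask),
    class = "template_space"
  )
}

#' @export
print.template_space <- function(x, ...) {
  cat("<template_space>\n")
  cat("  shape:   ", paste(x$shape, collapse = " x "), "voxels\n")
  cat("  spacing: ", paste(format(x$spacing), collapse = " x "), "mm\n")
  cat("  brain:   ", sum(x$brain_mask), "voxels\n")
  cat("  ventricle:", sum(x$ventricle_mask), "voxels\n")
  invisible(x)
}

#' World coordinates of every voxel centre
#'
#' Applies the template affine to the full 0-based voxel index grid.
#'
#' @param template A `template_space`.
#' @return List of three arrays (`x`, `y`, `z`), each of the grid shape, in mm.
#' @keywords internal
world_grid <- function(template) {
  d <- template$shape
  A <- template$affine
  i <- as.numeric(0:(d[1] - 1))
  j <- as.numeric(0:(d[2] - 1))
  k <- as.numeric(0:(d[3] - 1))
  axis_sum <- function(r) {
    outer(outer(A[r, 1] * i, A[r, 2] * j, `+`), A[r, 3] * k + A[r, 4], `+`)
  }
  list(x = axis_sum(1), y = axis_sum(2), z = axis_sum(3))
}

# Map 0-based voxel index rows (n x 3) to world mm coordinates (n x 3).
voxel_to_world <- function(ijk, template) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk, 1) %*% t(template$affine)
  h[, 1:3, drop = FALSE]
}

# Map world mm coordinates (n x 3) to 0-based (fractional) voxel indices.
world_to_voxel <- function(xyz, template) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  h <- cbind(xyz, 1) %*% t(solve(template$affine))
  h[, 1:3, drop = FALSE]
}

#' Build a synthetic template space
#'
#' Constructs a deterministic toy analogue of a standard brain template: an
#' ellipsoidal brain mask centred in the grid and two parallel ellipsoidal
#' lateral-ventricle components straddling the mid-sagittal plane (`x = 0`
#' in world coordinates). This is the stand-in for a registered template used
#' by the synthetic cohorts; nothing about it is random.
#'
#' @param shape Integer length-3 grid size, each component >= 16.
#' @param spacing Positive length-3 voxel spacing in mm.
#' @param ventricle_spec List of geometry parameters (all in mm):
#'   `offset_mm` lateral offset of each ventricle centre from the midline;
#'   `radius_mm` length-3 semi-axes of each ventricle ellipsoid;
#'   `brain_shrink` fraction of the half field-of-view used for the brain
#'   ellipsoid semi-axes (default 0.9).
#' @return A [template_space()].
#' @examples
#' tpl <- make_template(c(32, 32, 32), c(2, 2, 2))
#' sum(tpl$ventricle_mask & !tpl$brain_mask) # 0: ventricles inside brain
#' @export
make_template <- function(shape = c(64, 64, 64), spacing = c(2, 2, 2),
                          ventricle_spec = list()) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    stopf("shape must be >= 16 voxels along every axis")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stopf("spacing must be strictly positive")
  }
  spec <- utils::modifyList(
    list(offset_mm = NULL, radius_mm = NULL, brain_shrink = 0.9),
    ventricle_spec
  )
  half_fov <- (shape - 1) * spacing / 2
  brain_semi <- spec$brain_shrink * half_fov
  if (is.null(spec$offset_mm)) spec$offset_mm <- 0.18 * (2 * half_fov[1])
  if (is.null(spec$radius_mm)) {
    spec$radius_mm <- c(0.05, 0.28, 0.10) * (2 * half_fov)
  }
  spec$radius_mm <- rep_len(as.numeric(spec$radius_mm), 3L)

  centre <- (shape - 1) / 2
  affine <- rbind(cbind(diag(spacing), -spacing * centre), c(0, 0, 0, 1))
  tmp <- list(shape = shape, spacing = spacing, affine = affine)
  g <- world_grid(structure(tmp, class = "template_space"))

  brain <- (g$x / brain_semi[1])^2 + (g$y / brain_semi[2])^2 +
    (g$z / brain_semi[3])^2 <= 1
  vent <- array(FALSE, shape)
  for (side in c(-1, 1)) {
    cx <- side * spec$offset_mm
    vent <- vent |
      ((g$x - cx) / spec$radius_mm[1])^2 +
      (g$y / spec$radius_mm[2])^2 +
      (g$z / spec$radius_mm[3])^2 <= 1
  }
  if (!any(vent)) stopf("ventricle_spec produced an empty ventricle mask")
  if (any(vent & !brain)) {
    stopf(paste("ventricle_spec places ventricle voxels outside the brain",
                "ellipsoid, violating the ventricle-within-brain invariant"))
  }
  template_space(shape, spacing, affine, brain, vent)
}
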