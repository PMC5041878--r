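#' Tumor density map for a group of subjects
#'
#' Per-voxel number of subjects whose (filled) CE mask covers the voxel, and
#' the corresponding probability: count divided by the number of subjects.
#'
#' @param masks List of binary 3-D arrays, all of the same shape.
#' @param group_label Name for the group (e.g. `"all"` or a subtype).
#' @return A `density_map`: list with `counts` (integer array), `probability`
#'   (numeric array in \[0, 1\]), `n_subjects`, `group_label`.
#' @export
density_map <- function(masks, group_label = "all") {
  if (length(masks) == 0L) stopf("density_map needs at least one mask")
  masks <- lapply(masks, as_mask)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) all(dim(m) == d), logical(1)))) {
    stopf("all masks must share one grid shape")
  }
  counts <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), d)))
  structure(
    list(counts = counts, probability = counts / length(masks),
         n_subjects = length(masks), group_label = group_label),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map '%s'> n = %d subjects, max overlap = %d (%.3f)\n",
              x$group_label, x$n_subjects, max(x$counts), max(x$probability)))
  invisible(x)
}

#' Centroid density map
#'
#' Density map built from a fixed-radius sphere (default 15 mm) placed at the
#' centre of mass of each subject's filled CE volume, summarising where
#' tumors are centred rather than where they extend.
#'
#' @param records List of `subject_record`s (filled).
#' @param template A [template_space()].
#' @param radius_mm Sphere radius in mm.
#' @param group_label Name for the group.
#' @return A `density_map`.
#' @export
centroid_density_map <- function(records, template, radius_mm = 15,
                                 group_label = "all") {
  spheres <- lapply(records, function(r) {
    centroid_sphere(centroid(as_mask(r$ce_mask), template), radius_mm, template)
  })
  density_map(spheres, group_label)
}

#' Periventricular enrichment of a density map
#'
#' How much of the tumor density mass sits within `band_mm` of the lateral
#' ventricles, against how much of the brain that band occupies. The band is
#' the set of brain-mask voxels whose Euclidean distance to the nearest
#' ventricle voxel is at most `band_mm` (ventricle voxels included, at
#' distance 0).
#'
#' @param dmap A `density_map` on the template grid.
#' @param template A [template_space()].
#' @param band_mm Band width in mm (default 10).
#' @param distance Optional precomputed [distance_transform()] of `template`.
#' @param mode `"mass"` (default): mass_fraction is the probability-weighted
#'   share, sum of probability over the band divided by the total sum.
#'   `"presence"`: the share of distinct tumor-bearing voxels
#'   (probability > 0) that lie in the band.
#' @return List: `mass_fraction`, `volume_fraction`, `band_mm`,
#'   `band_voxels`, `brain_voxels` — fractions in \[0, 1\].
#' @export
periventricular_fraction <- function(dmap, template, band_mm = 10,
                                     distance = NULL,
                                     mode = c("mass", "presence")) {
  mode <- match.arg(mode)
  if (!all(dim(dmap$probability) == template$shape)) {
    stopf("density map shape does not match the template grid")
  }
  if (!is.finite(band_mm) || band_mm < 0) stopf("band_mm must be >= 0")
  total <- sum(dmap$probability)
  if (total == 0) stopf("density map is all zero; mass fraction undefined")
  if (is.null(distance)) distance <- distance_transform(template)
  band <- template$brain_mask & (distance$values <= band_mm)
  mass_fraction <- if (mode == "mass") {
    sum(dmap$probability[band]) / total
  } else {
    present <- dmap$probability > 0
    sum(present & band) / sum(present)
  }
  list(
    mass_fraction = mass_fraction,
    volume_fraction = sum(band) / sum(template$brain_mask),
    band_mm = band_mm,
    band_voxels = sum(band),
    brain_voxels = sum(template$brain_mask)
  )
}
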