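#' Glioblastoma subtype labels
#'
#' Canonical label set: the four transcriptomic classes, the G-CIMP
#' methylator phenotype, and `unknown` for unclassified subjects.
#' @export
SUBTYPES <- c("proneural", "neural", "classical", "mesenchymal",
              "gcimp", "unknown")

match_subtype <- function(x, context = "subtype") {
  m <- match(tolower(trimws(x)), SUBTYPES)
  if (anyNA(m)) {
    stopf("%s '%s' is not one of: %s", context,
          paste(x[is.na(m)], collapse = ", "), paste(SUBTYPES, collapse = ", "))
  }
  SUBTYPES[m]
}

#' One subject of the cohort
#'
#' @param subject_id Unique identifier string.
#' @param subtype One of [SUBTYPES] (case-insensitive).
#' @param ce_mask Nonempty binary 3-D contrast-enhancing mask in template
#'   space.
#' @param filled Whether enclosed cavities have already been filled.
#' @param template Optional [template_space()]; when given, the mask is
#'   checked to lie within the brain mask.
#' @return A `subject_record`.
#' @export
subject_record <- function(subject_id, subtype, ce_mask, filled = FALSE,
                           template = NULL) {
  ce_mask <- as_mask(ce_mask, "ce_mask")
  if (!any(ce_mask)) stopf("subject %s: CE mask is empty", subject_id)
  if (!is.null(template)) {
    if (!all(dim(ce_mask) == template$shape)) {
      stopf("subject %s: mask shape (%s) does not match template grid (%s)",
            subject_id, paste(dim(ce_mask), collapse = "x"),
            paste(template$shape, collapse = "x"))
    }
    if (any(ce_mask & !template$brain_mask)) {
      stopf("subject %s: CE mask extends outside the template brain mask",
            subject_id)
    }
  }
  structure(
    list(subject_id = as.character(subject_id),
         subtype = match_subtype(subtype),
         ce_mask = ce_mask, filled = isTRUE(filled)),
    class = "subject_record"
  )
}

#' Fill all subject masks that are not yet filled
#'
#' @param records List of `subject_record`s.
#' @return The records, each with a hole-free mask and `filled = TRUE`.
#' @export
fill_records <- function(records) {
  lapply(records, function(r) {
    if (!r$filled) {
      r$ce_mask <- fill_ce_volume(r$ce_mask)
      r$filled <- TRUE
    }
    r
  })
}

#' Configuration of a synthetic cohort
#'
#' Defines the spatial structure the generator emulates: how many subjects
#' per subtype, how far from the lateral ventricles each subtype's tumors
#' are centred (normal distribution of the centre-to-ventricle distance,
#' truncated to distances achievable inside the brain), the tumor size range,
#' and an optional left-hemisphere placement bias per subtype.
#'
#' Defaults mirror the structure of a moderate clinical cohort: subtype
#' proportions follow typical molecular-subtype frequencies at a total of 60
#' subjects; proneural/neural tumors are centred near the ventricles with a
#' left bias, classical/mesenchymal farther out and symmetric.
#'
#' @param n_per_subtype Named integer vector (names from [SUBTYPES]).
#' @param center_distance_mean,center_distance_sd Named numeric vectors, mm.
#' @param tumor_radius_range Length-2 numeric, min/max tumor radius in mm;
#'   radii are drawn uniformly.
#' @param laterality_bias Named numeric vector in \[0, 1\]: probability that
#'   a tumor centre is placed in the left hemisphere (world x < 0).
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @param max_retries Rejection-sampling retry cap per tumor.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(
    n_per_subtype = c(proneural = 13, neural = 11, classical = 14,
                      mesenchymal = 16, gcimp = 3, unknown = 3),
    center_distance_mean = c(proneural = 8, neural = 10, classical = 22,
                             mesenchymal = 25, gcimp = 8, unknown = 15),
    center_distance_sd = c(proneural = 4, neural = 4, classical = 4,
                           mesenchymal = 4, gcimp = 4, unknown = 4),
    tumor_radius_range = c(8, 16),
    laterality_bias = c(proneural = 0.7, neural = 0.7, classical = 0.5,
                        mesenchymal = 0.5, gcimp = 0.5, unknown = 0.5),
    seed = 42L,
    max_retries = 10000L) {
  fill_named <- function(x, default) {
    out <- stats::setNames(rep(default, length(SUBTYPES)), SUBTYPES)
    if (length(x)) {
      names(x) <- match_subtype(names(x))
      out[names(x)] <- x
    }
    out
  }
  n_per_subtype <- fill_named(n_per_subtype, 0L)
  center_distance_mean <- fill_named(center_distance_mean, 15)
  center_distance_sd <- fill_named(center_distance_sd, 4)
  laterality_bias <- fill_named(laterality_bias, 0.5)
  if (any(n_per_subtype < 0)) stopf("subject counts must be >= 0")
  if (any(center_distance_sd < 0)) stopf("distance sds must be >= 0")
  tumor_radius_range <- as.numeric(tumor_radius_range)
  if (length(tumor_radius_range) != 2L || tumor_radius_range[1] <= 0 ||
      tumor_radius_range[2] < tumor_radius_range[1]) {
    stopf("tumor_radius_range must satisfy 0 < min <= max")
  }
  if (any(laterality_bias < 0 | laterality_bias > 1)) {
    stopf("laterality_bias must lie in [0, 1]")
  }
  structure(
    list(n_per_subtype = as.integer(round(n_per_subtype)) |>
           stats::setNames(SUBTYPES),
         center_distance_mean = center_distance_mean,
         center_distance_sd = center_distance_sd,
         tumor_radius_range = tumor_radius_range,
         laterality_bias = laterality_bias,
         seed = as.integer(seed),
         max_retries = as.integer(max_retries)),
    class = "cohort_config"
  )
}

#' Sample one synthetic tumor mask
#'
#' Draws a solid sphere in world mm, intersected with the brain mask. The
#' centre is a brain voxel whose distance to the nearest ventricle voxel
#' matches a draw from the subtype's truncated normal distance distribution
#' (rejection sampling against the achievable distances, with a retry cap),
#' in the hemisphere chosen by the subtype's laterality bias. Consumes the
#' current R random stream; seed via [make_cohort()] or `set.seed()`.
#'
#' @param template A [template_space()].
#' @param subtype One of [SUBTYPES].
#' @param config A [cohort_config()].
#' @param dmap Optional precomputed [distance_transform()] of `template`.
#' @return Logical 3-D mask (hole-free by construction).
#' @export
sample_tumor <- function(template, subtype, config, dmap = NULL) {
  subtype <- match_subtype(subtype)
  if (is.null(dmap)) dmap <- distance_transform(template)
  mu <- config$center_distance_mean[[subtype]]
  sd <- config$center_distance_sd[[subtype]]
  p_left <- config$laterality_bias[[subtype]]

  brain_idx <- which(template$brain_mask)
  ijk <- arrayInd(brain_idx, template$shape) - 1
  wx <- voxel_to_world(ijk, template)[, 1]
  dist_v <- dmap$values[brain_idx]
  # match tolerance: half the voxel diagonal, so every achievable distance
  # has at least its own voxel as a candidate
  tol <- sqrt(sum(template$spacing^2)) / 2

  centre_lin <- NA_integer_
  for (try in seq_len(config$max_retries)) {
    left <- stats::runif(1) < p_left
    d <- stats::rnorm(1, mu, sd)
    if (d < 0) next
    cand <- if (left) wx < 0 else wx >= 0
    cand <- cand & abs(dist_v - d) <= tol
    n_cand <- sum(cand)
    if (n_cand == 0L) next
    pick <- if (n_cand == 1L) which(cand) else sample(which(cand), 1L)
    centre_lin <- brain_idx[pick]
    break
  }
  if (is.na(centre_lin)) {
    stopf(paste0("no achievable tumor centre for subtype '%s' after %d tries: ",
                 "requested distance ~N(%g, %g) mm, achievable range ",
                 "[%.1f, %.1f] mm"),
          subtype, config$max_retries, mu, sd, min(dist_v), max(dist_v))
  }
  centre <- voxel_to_world(arrayInd(centre_lin, template$shape) - 1, template)
  r <- stats::runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
  centroid_sphere(centre, r, template) & template$brain_mask
}

#' Generate a synthetic cohort
#'
#' Produces one `subject_record` per requested subject, consuming a single
#' seeded random stream in a fixed subject order (subtypes in [SUBTYPES]
#' order), so the cohort is bit-for-bit reproducible from `config$seed`.
#' Generated masks are convex (sphere intersected with the ellipsoidal
#' brain), hence hole-free, and are marked `filled`.
#'
#' @param template A [template_space()].
#' @param config A [cohort_config()].
#' @return List of `subject_record`s, length `sum(config$n_per_subtype)`.
#' @export
make_cohort <- function(template, config) {
  total <- sum(config$n_per_subtype)
  if (total == 0L) stopf("cohort has zero subjects")
  dmap <- distance_transform(template)
  with_seed(config$seed, {
    records <- vector("list", total)
    i <- 0L
    for (st in SUBTYPES) {
      for (rep in seq_len(config$n_per_subtype[[st]])) {
        i <- i + 1L
        mask <- sample_tumor(template, st, config, dmap)
        records[[i]] <- subject_record(
          sprintf("sub-%03d", i), st, mask, filled = TRUE, template = template
        )
      }
    }
    records
  })
}
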