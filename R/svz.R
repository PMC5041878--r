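#' Euclidean distance transform of the ventricle mask
#'
#' Exact Euclidean distance, in world mm, from every voxel centre to the
#' nearest ventricle voxel centre, honouring anisotropic voxel spacing.
#' Ventricle voxels have distance 0; approaching the ventricular border from
#' outside, this equals the distance to the border itself, so no explicit
#' surface extraction is needed. Computed with the separable lower-envelope
#' (squared-parabola) algorithm, one pass per axis, which is exact for the
#' Euclidean metric on an axis-aligned grid.
#'
#' @param template A [template_space()] with a nonempty ventricle mask. The
#'   affine is assumed orthogonal (axis-aligned), the standard situation for
#'   registered template space; spacing is taken from the affine column norms.
#' @return A `distance_map`: list with `values` (3-D array, mm) and
#'   `spacing` (mm).
#' @export
distance_transform <- function(template) {
  if (!any(template$ventricle_mask)) stopf("ventricle mask is empty")
  spacing <- sqrt(colSums(template$affine[1:3, 1:3]^2))
  sq <- edt_squared(template$ventricle_mask, spacing)
  structure(list(values = sqrt(sq), spacing = spacing), class = "distance_map")
}

# Squared anisotropic EDT of `mask` (distance to nearest TRUE voxel).
edt_squared <- function(mask, spacing) {
  d <- dim(mask)
  f <- array(ifelse(mask, 0, Inf), d)
  for (axis in 1:3) {
    n <- d[axis]
    if (n == 1L) next
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(f, perm), nrow = n)
    m <- apply(m, 2, edt_1d, w = spacing[axis])
    f <- aperm(array(m, d[perm]), order(perm))
  }
  f
}

# 1-D squared distance transform of sampled function f on a grid with
# spacing w (Felzenszwalb & Huttenlocher lower envelope of parabolas).
edt_1d <- function(f, w) {
  n <- length(f)
  if (all(!is.finite(f))) return(f)
  w2 <- w * w
  v <- integer(n)  # parabola apex indices
  z <- numeric(n + 1L)  # envelope breakpoints
  k <- 1L
  v[1L] <- which(is.finite(f))[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  idx <- which(is.finite(f))
  for (q in idx[-1L]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + w2 * (q - 1)^2) - (f[p] + w2 * (p - 1)^2)) /
        (2 * w2 * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
        next
      }
      break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q - 1) k <- k + 1L
    p <- v[k]
    out[q] <- w2 * (q - p)^2 + f[p]
  }
  out
}

#' Per-subject SVZ distance
#'
#' Mean of the ventricular distance transform over all voxels of the
#' subject's filled contrast-enhancing volume, i.e. the average distance (mm)
#' from each tumor voxel to the nearest lateral-ventricle voxel. Tumor voxels
#' inside the ventricle lumen contribute distance 0.
#'
#' @param record A `subject_record` (filled mask).
#' @param dmap A `distance_map` from [distance_transform()].
#' @return Nonnegative scalar, mm.
#' @export
svz_distance <- function(record, dmap) {
  mask <- as_mask(record$ce_mask)
  if (!any(mask)) stopf("subject %s has an empty CE mask", record$subject_id)
  if (!all(dim(mask) == dim(dmap$values))) {
    stopf("mask and distance map shapes differ")
  }
  mean(dmap$values[mask])
}

#' SVZ distance table for a cohort
#'
#' @param records List of `subject_record`s (filled).
#' @param template A [template_space()].
#' @param dmap Optional precomputed [distance_transform()] of `template`.
#' @return data.frame with columns `subject_id`, `subtype`,
#'   `svz_distance_mm`, `ce_voxels` (one row per subject).
#' @export
svz_distance_table <- function(records, template, dmap = NULL) {
  if (is.null(dmap)) dmap <- distance_transform(template)
  data.frame(
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    subtype = vapply(records, function(r) r$subtype, character(1)),
    svz_distance_mm = vapply(records, svz_distance, numeric(1), dmap = dmap),
    ce_voxels = vapply(records, function(r) sum(as_mask(r$ce_mask)), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Compare SVZ distances between two subtype groups
#'
#' Two-sample two-tailed Student's t-test (pooled variance by default;
#' `welch = TRUE` drops the equal-variance assumption) on per-subject SVZ
#' distances, with group means and medians.
#'
#' @param table data.frame from [svz_distance_table()].
#' @param group_a,group_b Character vectors of subtype labels defining the
#'   two groups (e.g. `c("proneural", "neural")`).
#' @param welch Use Welch's unequal-variance t-test instead of pooled.
#' @return One-row data.frame: `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `median_a`, `median_b`, `t_statistic`, `degrees_of_freedom`,
#'   `p_value`.
#' @export
compare_groups <- function(table, group_a, group_b, welch = FALSE) {
  xa <- table$svz_distance_mm[table$subtype %in% group_a]
  xb <- table$svz_distance_mm[table$subtype %in% group_b]
  if (length(xa) < 2L || length(xb) < 2L) {
    stopf("both groups need >= 2 subjects (got %d and %d)",
          length(xa), length(xb))
  }
  if (stats::var(xa) + stats::var(xb) == 0) {
    stopf("zero pooled variance: SVZ distances are constant within '%s' and '%s'",
          paste(group_a, collapse = "+"), paste(group_b, collapse = "+"))
  }
  tt <- stats::t.test(xa, xb, var.equal = !welch)
  data.frame(
    group_a = paste(group_a, collapse = "+"),
    group_b = paste(group_b, collapse = "+"),
    n_a = length(xa), n_b = length(xb),
    mean_a = mean(xa), mean_b = mean(xb),
    median_a = stats::median(xa), median_b = stats::median(xb),
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = tt$p.value,
    stringsAsFactors = FALSE
  )
}

#' Standard subtype SVZ-distance contrasts
#'
#' The default report: the four pairwise contrasts of {proneural, neural}
#' against {classical, mesenchymal}, plus the combined
#' proneural+neural vs classical+mesenchymal contrast.
#'
#' @inheritParams compare_groups
#' @return data.frame with one row per contrast (see [compare_groups()]).
#' @export
svz_group_comparisons <- function(table, welch = FALSE) {
  contrasts <- list(
    list(a = "proneural", b = "classical"),
    list(a = "proneural", b = "mesenchymal"),
    list(a = "neural", b = "classical"),
    list(a = "neural", b = "mesenchymal"),
    list(a = c("proneural", "neural"), b = c("classical", "mesenchymal"))
  )
  do.call(rbind, lapply(contrasts, function(ct) {
    compare_groups(table, ct$a, ct$b, welch = welch)
  }))
}
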