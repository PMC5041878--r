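#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability (minimum-likelihood)
#' rule: with both margins fixed, sum the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed table
#' (relative tolerance 1e-9 for floating-point ties). The table layout is
#' tumor presence at one voxel: `a` subtype subjects with tumor, `b` without,
#' `c` other subjects with tumor, `d` without.
#'
#' @param a,b,c,d Nonnegative integer cells; alternatively `a` may be a
#'   length-4 vector `(a, b, c, d)`.
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(3, 0, 0, 3) # 0.1
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    v <- as.numeric(a)
    if (length(v) != 4L) stopf("need 4 cells")
    a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  }
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stopf("table cells must be nonnegative integers")
  }
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 + r2 == 0) stopf("at least one margin must be positive")
  x <- max(0, k - r2):min(k, r1)
  probs <- stats::dhyper(x, r1, r2, k)
  p_obs <- stats::dhyper(a, r1, r2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# p-value lookup for all (a, c) given fixed group sizes n1 (subtype) and n2
# (rest): entry [a + 1, c + 1] is fisher_exact_2x2(a, n1 - a, c, n2 - c).
# Margins are invariant under label permutation, so one lookup serves all
# permutations of a cohort.
fisher_p_lookup <- function(n1, n2) {
  out <- matrix(NA_real_, n1 + 1L, n2 + 1L)
  for (a in 0:n1) {
    for (c in 0:n2) {
      out[a + 1L, c + 1L] <- fisher_exact_2x2(a, n1 - a, c, n2 - c)
    }
  }
  out
}

# Shared scaffolding for the voxel-wise subtype tests: subjects with a known
# subtype, their mask matrix restricted to brain voxels, and the one-vs-rest
# indicator for `subtype`.
subtype_test_data <- function(records, subtype, template) {
  subtype <- match_subtype(subtype)
  labels <- vapply(records, function(r) r$subtype, character(1))
  keep <- labels != "unknown"
  if (!any(labels[keep] == subtype)) {
    stopf("subtype '%s' absent from the cohort", subtype)
  }
  if (length(unique(labels[keep])) < 2L) {
    stopf("need at least two subtype groups (after excluding 'unknown')")
  }
  records <- records[keep]
  labels <- labels[keep]
  brain_idx <- which(template$brain_mask)
  M <- vapply(records, function(r) {
    m <- as_mask(r$ce_mask)
    if (!all(dim(m) == template$shape)) {
      stopf("subject %s: mask shape does not match the template", r$subject_id)
    }
    as.numeric(m[brain_idx])
  }, numeric(length(brain_idx)))
  is_s <- labels == subtype
  list(subtype = subtype, M = M, is_s = is_s, brain_idx = brain_idx,
       n1 = sum(is_s), n2 = sum(!is_s), tot = rowSums(M))
}

#' Voxel-wise subtype-vs-rest Fisher test
#'
#' At every brain voxel touched by at least one tumor, tests whether filled
#' CE masks of the given subtype cover the voxel more (or less) often than
#' those of all other subtypes, with a two-tailed Fisher's exact test on the
#' presence/absence 2x2 table. Subjects labelled `unknown` are excluded from
#' both margins. Voxels with no tumor overlap, and voxels outside the brain
#' mask, get p = 1 so the map is dense and shape-stable.
#'
#' @param records List of `subject_record`s (filled masks).
#' @param subtype Subtype to contrast against the rest.
#' @param template A [template_space()].
#' @return Numeric 3-D array of p-values in (0, 1].
#' @export
voxelwise_subtype_test <- function(records, subtype, template) {
  td <- subtype_test_data(records, subtype, template)
  lookup <- fisher_p_lookup(td$n1, td$n2)
  a <- as.numeric(td$M %*% td$is_s)
  cc <- td$tot - a
  p <- array(1, template$shape)
  testable <- td$tot > 0
  p[td$brain_idx[testable]] <-
    lookup[cbind(a[testable] + 1, cc[testable] + 1)]
  p
}

# Largest 26-connected component size among suprathreshold brain voxels
# given by linear indices; 0 when none.
max_cluster_size <- function(lin, shape) {
  if (length(lin) == 0L) return(0L)
  m <- array(FALSE, shape)
  m[lin] <- TRUE
  lab <- label_components(m)
  max(tabulate(lab[lab > 0L]))
}

#' Permutation-based cluster-level filtering of a subtype p-map
#'
#' Thresholds the voxel-wise p-map at `voxel_alpha`, labels 26-connected
#' suprathreshold clusters, and keeps those unlikely to arise by chance:
#' subtype labels are permuted across subjects `n_permutations` times, the
#' full voxel-wise Fisher test is recomputed for each relabelling (margins
#' are permutation-invariant, so the exact p-values come from one
#' margin-indexed lookup), and the largest suprathreshold cluster size per
#' permutation forms the null. Cluster-level p-values use the add-one rule
#' `(1 + #{null max >= size}) / (n_permutations + 1)`, controlling
#' family-wise error; clusters with `cluster_p <= cluster_alpha` are
#' retained.
#'
#' @param p_map Voxel-wise p-map from [voxelwise_subtype_test()] on the same
#'   records.
#' @param records,subtype,template As in [voxelwise_subtype_test()].
#' @param voxel_alpha Voxel-level threshold (clusters are voxels with
#'   `p < voxel_alpha`).
#' @param cluster_alpha Cluster-level retention threshold.
#' @param n_permutations Number of label permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @return A `cluster_result`: list with `subtype`, `p_map`, `voxel_alpha`,
#'   `cluster_alpha`, `cluster_labels` (integer array, 0 = background),
#'   `cluster_sizes`, `cluster_p`, `retained`, `perm_max_sizes`,
#'   `n_permutations`, `seed`.
#' @export
cluster_filter <- function(p_map, records, subtype, template,
                           voxel_alpha = 0.05, cluster_alpha = 0.05,
                           n_permutations = 1000L, seed = 1L) {
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stopf("n_permutations must be >= 1")
  td <- subtype_test_data(records, subtype, template)
  if (!all(dim(p_map) == template$shape)) {
    stopf("p_map shape does not match the template grid")
  }
  lookup <- fisher_p_lookup(td$n1, td$n2)
  n <- length(td$is_s)

  supra <- array(p_map < voxel_alpha, template$shape)
  labels <- label_components(supra)
  n_clust <- max(labels)
  sizes <- if (n_clust > 0L) tabulate(labels[labels > 0L], n_clust) else integer(0)

  # null distribution of the maximum cluster size under label permutation;
  # only voxels with any tumor overlap can change, so the mask matrix is
  # restricted to them, and permutations are processed in blocks to bound
  # memory on large grids
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) as.numeric(sample(td$is_s)),
           numeric(n))
  })
  testable <- td$tot > 0
  Mt <- td$M[testable, , drop = FALSE]
  tot_t <- td$tot[testable]
  idx_t <- td$brain_idx[testable]
  perm_max <- integer(n_permutations)
  lut <- as.numeric(lookup)
  nr <- nrow(lookup)
  block <- 100L
  for (start in seq(1L, n_permutations, by = block)) {
    cols <- start:min(start + block - 1L, n_permutations)
    A <- Mt %*% perm[, cols, drop = FALSE]  # a-counts, voxels x perms
    for (jj in seq_along(cols)) {
      at <- A[, jj]
      pv <- lut[(at + 1) + nr * (tot_t - at)]
      hit <- idx_t[pv < voxel_alpha]
      perm_max[cols[jj]] <- max_cluster_size(hit, template$shape)
    }
  }

  cluster_p <- vapply(sizes, function(s) {
    (1 + sum(perm_max >= s)) / (n_permutations + 1)
  }, numeric(1))
  retained <- cluster_p <= cluster_alpha
  keep_labels <- labels
  if (n_clust > 0L) {
    drop <- which(!retained)
    if (length(drop)) keep_labels[labels %in% drop] <- 0L
  }
  structure(
    list(subtype = td$subtype, p_map = p_map, voxel_alpha = voxel_alpha,
         cluster_alpha = cluster_alpha,
         cluster_labels = labels, retained_labels = keep_labels,
         cluster_sizes = sizes, cluster_p = cluster_p, retained = retained,
         perm_max_sizes = perm_max,
         n_permutations = n_permutations, seed = as.integer(seed)),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result '%s'> %d cluster(s), %d retained (n_perm = %d)\n",
              x$subtype, length(x$cluster_sizes), sum(x$retained),
              x$n_permutations))
  invisible(x)
}

#' Cluster table of a cluster_result
#'
#' @param x A `cluster_result`.
#' @return data.frame: `cluster_id`, `size_voxels`, `cluster_p`, `retained`,
#'   `peak_i`, `peak_j`, `peak_k` (1-based index of the lowest-p voxel).
#' @export
cluster_table <- function(x) {
  n <- length(x$cluster_sizes)
  if (n == 0L) {
    return(data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      cluster_p = numeric(0), retained = logical(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0)))
  }
  peaks <- t(vapply(seq_len(n), function(id) {
    lin <- which(x$cluster_labels == id)
    arrayInd(lin[which.min(x$p_map[lin])], dim(x$cluster_labels))[1, ]
  }, integer(3)))
  data.frame(cluster_id = seq_len(n), size_voxels = x$cluster_sizes,
             cluster_p = x$cluster_p, retained = x$retained,
             peak_i = peaks[, 1], peak_j = peaks[, 2], peak_k = peaks[, 3])
}
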