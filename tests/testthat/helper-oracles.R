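# Small templates and independent brute-force oracles used across tests.
# The oracles deliberately share no code with the package internals.

small_template <- function(shape = c(24, 24, 24), spacing = c(2, 2, 2), ...) {
  make_template(shape, spacing, ...)
}

# Brute-force anisotropic Euclidean distance (mm) to the nearest TRUE voxel:
# direct min over the reference voxel set, chunked over target voxels.
brute_distance <- function(mask, spacing) {
  d <- dim(mask)
  ref <- (arrayInd(which(mask), d) - 1) %*% diag(spacing)
  out <- array(NA_real_, d)
  all_idx <- seq_len(prod(d))
  for (chunk in split(all_idx, ceiling(all_idx / 4096))) {
    pts <- (arrayInd(chunk, d) - 1) %*% diag(spacing)
    d2 <- outer(rowSums(pts^2), rowSums(ref^2), `+`) -
      2 * pts %*% t(ref)
    out[chunk] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# Exhaustive two-tailed Fisher p: enumerate every table with the observed
# margins, compute each probability from binomial coefficients, and sum
# those no larger than the observed table's probability.
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  ts <- max(0, k - r2):min(k, r1)
  pr <- choose(r1, ts) * choose(r2, k - ts) / choose(n, k)
  p_obs <- choose(r1, a) * choose(r2, k - a) / choose(n, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# Two-sided Student-t p-value via the incomplete beta function, independent
# of stats::pt.
beta_t_pvalue <- function(t, df) {
  pbeta(df / (df + t^2), df / 2, 0.5)
}

# Flood fill background from the array boundary (6-connectivity), one voxel
# at a time with an explicit queue; the filled mask is the complement.
brute_fill <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  seen <- array(FALSE, d)
  queue <- which(bg & {
    edge <- array(FALSE, d)
    edge[c(1, d[1]), , ] <- TRUE; edge[, c(1, d[2]), ] <- TRUE
    edge[, , c(1, d[3])] <- TRUE
    edge
  })
  seen[queue] <- TRUE
  off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ijk <- arrayInd(cur, d)
    for (r in seq_len(6)) {
      nb <- ijk + off[r, ]
      if (any(nb < 1) || any(nb > d)) next
      lin <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
      if (bg[lin] && !seen[lin]) {
        seen[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
  }
  !seen
}

# A random lumpy blob: union of a few spheres on a small grid.
random_blob <- function(d = c(14, 14, 14), n_spheres = 3) {
  g <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  m <- array(FALSE, d)
  for (s in seq_len(n_spheres)) {
    ctr <- runif(3, 4, d - 3)
    r <- runif(1, 2, 4)
    m <- m | array((g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2 <= r^2, d)
  }
  if (!any(m)) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
  m
}

# Hollow 5x5x5 cube fixture: 98 shell voxels around an empty 3x3x3 cavity.
hollow_cube <- function() {
  m <- array(FALSE, c(9, 9, 9))
  m[3:7, 3:7, 3:7] <- TRUE
  m[4:6, 4:6, 4:6] <- FALSE
  m
}
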