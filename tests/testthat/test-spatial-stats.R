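test_that("two-tailed Fisher p-values match exhaustive enumeration", {
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 5), 1)
  expect_equal(fisher_exact_2x2(2, 8, 8, 2), brute_fisher(2, 8, 8, 2),
               tolerance = 1e-12)
  # agreement with the reference implementation on assorted tables
  for (tb in list(c(1, 9, 7, 3), c(5, 5, 5, 5), c(0, 10, 4, 6),
                  c(12, 0, 3, 9), c(2, 3, 4, 1))) {
    expect_equal(
      fisher_exact_2x2(tb),
      stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
      tolerance = 1e-9
    )
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "margin")
})

test_that("Fisher p is invariant under simultaneous row and column swap", {
  set.seed(5)
  for (i in 1:50) {
    tb <- rpois(4, 4)
    if (sum(tb) == 0) next
    # (a b / c d) -> (d c / b a): swap rows then columns
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 fisher_exact_2x2(tb[4], tb[3], tb[2], tb[1]),
                 tolerance = 1e-12)
  }
})

test_that("voxel-wise subtype maps give exact one-vs-rest p-values", {
  tpl <- small_template(c(16, 16, 16), c(2, 2, 2))
  blank <- function() array(FALSE, tpl$shape)
  # 3 proneural all covering voxel v; 3 classical never covering it
  v <- c(8, 8, 8)
  recs <- c(
    lapply(1:3, function(i) {
      m <- blank(); m[v[1] + (0:1), v[2], v[3]] <- TRUE
      subject_record(paste0("p", i), "proneural", m, filled = TRUE)
    }),
    lapply(1:3, function(i) {
      m <- blank(); m[6:7, 11, 8] <- TRUE
      subject_record(paste0("c", i), "classical", m, filled = TRUE)
    })
  )
  p <- voxelwise_subtype_test(recs, "proneural", tpl)
  expect_equal(p[v[1], v[2], v[3]], 0.1)
  expect_equal(p[6, 11, 8], 0.1)   # the mirrored voxel: 0 vs 3
  expect_equal(p[15, 15, 15], 1)   # untouched voxel
  expect_equal(dim(p), tpl$shape)
  expect_true(all(p > 0 & p <= 1))

  # identical masks in both groups: no signal anywhere
  same <- c(
    lapply(1:3, function(i) {
      m <- blank(); m[6:9, 6:9, 6:9] <- TRUE
      subject_record(paste0("s", i), "neural", m, filled = TRUE)
    }),
    lapply(1:3, function(i) {
      m <- blank(); m[6:9, 6:9, 6:9] <- TRUE
      subject_record(paste0("t", i), "mesenchymal", m, filled = TRUE)
    })
  )
  expect_true(all(voxelwise_subtype_test(same, "neural", tpl) == 1))

  # unknown subjects are excluded from both margins
  with_unknown <- c(recs, list(subject_record("u1", "unknown", {
    m <- blank(); m[v[1], v[2], v[3]] <- TRUE; m
  }, filled = TRUE)))
  expect_equal(voxelwise_subtype_test(with_unknown, "proneural", tpl), p)

  expect_error(voxelwise_subtype_test(recs, "gcimp", tpl), "absent")
  expect_error(voxelwise_subtype_test(recs[1:3], "proneural", tpl),
               "two subtype groups")
})

test_that("null label shuffles keep the sub-0.05 voxel fraction near or below 5%", {
  tpl <- small_template(c(20, 20, 20), c(2, 2, 2))
  set.seed(13)
  masks <- lapply(1:24, function(i) {
    sample_tumor(tpl, "neural",
                 cohort_config(center_distance_mean = c(neural = 10),
                               center_distance_sd = c(neural = 5),
                               tumor_radius_range = c(4, 8)))
  })
  fracs <- vapply(1:30, function(rep) {
    lab <- sample(rep(c("proneural", "classical"), each = 12))
    recs <- Map(function(m, l, i) subject_record(paste0("s", i), l, m,
                                                 filled = TRUE),
                masks, lab, seq_along(masks))
    p <- voxelwise_subtype_test(recs, "proneural", tpl)
    tot <- Reduce(`+`, masks)
    testable <- tpl$brain_mask & tot > 0
    mean(p[testable] < 0.05)
  }, numeric(1))
  # the exact test is conservative: average false-positive fraction <= ~5%
  expect_lte(mean(fracs), 0.05 + 0.02)
})

test_that("cluster filtering retains truly subtype-specific regions", {
  tpl <- small_template(c(20, 20, 20), c(2, 2, 2))
  blank <- function() array(FALSE, tpl$shape)
  set.seed(29)
  # proneural tumors share a block never touched by the rest
  recs <- c(
    lapply(1:6, function(i) {
      m <- blank(); m[4:8, 4:8, 8:12] <- TRUE
      subject_record(paste0("p", i), "proneural", m, filled = TRUE)
    }),
    lapply(1:6, function(i) {
      m <- blank(); m[13:17, 13:17, 8:12] <- TRUE
      subject_record(paste0("m", i), "mesenchymal", m, filled = TRUE)
    })
  )
  p <- voxelwise_subtype_test(recs, "proneural", tpl)
  cr <- cluster_filter(p, recs, "proneural", tpl, n_permutations = 200,
                       seed = 7)
  expect_s3_class(cr, "cluster_result")
  expect_gt(length(cr$cluster_sizes), 0)
  expect_true(any(cr$retained))
  # the retained cluster covers the in-brain part of the proneural block
  block <- blank(); block[4:8, 4:8, 8:12] <- TRUE
  expect_true(all(cr$cluster_labels[block & tpl$brain_mask] %in%
                    which(cr$retained)))
  # suprathreshold voxels all below the voxel alpha
  expect_true(all(cr$p_map[cr$cluster_labels > 0] < cr$voxel_alpha))
  # add-one floor: a cluster beating every permutation gets 1/(n+1)
  expect_equal(min(cr$cluster_p), 1 / 201)
  expect_true(all(cr$cluster_p > 0 & cr$cluster_p <= 1))
  expect_identical(cr$retained, cr$cluster_p <= cr$cluster_alpha)

  # same seed reproduces the result exactly
  cr2 <- cluster_filter(p, recs, "proneural", tpl, n_permutations = 200,
                        seed = 7)
  expect_identical(cr[names(cr) != "p_map"], cr2[names(cr2) != "p_map"])

  # cluster table structure
  tab <- cluster_table(cr)
  expect_identical(nrow(tab), length(cr$cluster_sizes))
  expect_true(all(tab$cluster_p[tab$retained] <= 0.05))

  expect_error(cluster_filter(p, recs, "proneural", tpl, n_permutations = 0),
               ">= 1")
})

test_that("a flat p-map yields no clusters", {
  tpl <- small_template(c(16, 16, 16), c(2, 2, 2))
  recs <- c(
    lapply(1:3, function(i) {
      m <- array(FALSE, tpl$shape); m[7:9, 7:9, 7:9] <- TRUE
      subject_record(paste0("a", i), "proneural", m, filled = TRUE)
    }),
    lapply(1:3, function(i) {
      m <- array(FALSE, tpl$shape); m[7:9, 7:9, 7:9] <- TRUE
      subject_record(paste0("b", i), "classical", m, filled = TRUE)
    })
  )
  p <- voxelwise_subtype_test(recs, "proneural", tpl) # all ones
  cr <- cluster_filter(p, recs, "proneural", tpl, n_permutations = 50,
                       seed = 1)
  expect_length(cr$cluster_sizes, 0)
  expect_length(cr$cluster_p, 0)
  expect_identical(max(cr$cluster_labels), 0L)
  expect_identical(nrow(cluster_table(cr)), 0L)
})
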