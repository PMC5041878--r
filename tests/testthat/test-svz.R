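make_point_template <- function(shape = c(12, 12, 12), spacing = c(1, 1, 1),
                                vent_at = c(6, 6, 6)) {
  brain <- array(TRUE, shape)
  vent <- array(FALSE, shape)
  vent[vent_at[1], vent_at[2], vent_at[3]] <- TRUE
  template_space(shape, spacing,
                 affine = rbind(cbind(diag(spacing), c(0, 0, 0)), c(0, 0, 0, 1)),
                 brain_mask = brain, ventricle_mask = vent)
}

test_that("distance transform is exact for a point ventricle", {
  tpl <- make_point_template()
  dm <- distance_transform(tpl)
  expect_equal(dm$values[6, 6, 6], 0)
  expect_equal(dm$values[6, 6, 9], 3)          # axis-aligned offset
  expect_equal(dm$values[7, 7, 6], sqrt(2))    # diagonal offset
  expect_equal(dm$values[8, 9, 12], sqrt(4 + 9 + 36))

  # anisotropic spacing: one voxel along z is 2 mm
  tpl2 <- make_point_template(spacing = c(1, 1, 2))
  dm2 <- distance_transform(tpl2)
  expect_equal(dm2$values[6, 6, 7], 2)
  expect_equal(dm2$values[7, 6, 7], sqrt(1 + 4))

  expect_error(
    distance_transform(structure(
      list(shape = c(4L, 4L, 4L), spacing = c(1, 1, 1), affine = diag(4),
           brain_mask = array(TRUE, c(4, 4, 4)),
           ventricle_mask = array(FALSE, c(4, 4, 4))),
      class = "template_space")),
    "empty"
  )
})

test_that("distance transform matches the brute-force scan exactly", {
  set.seed(47)
  for (i in 1:8) {
    shape <- sample(8:20, 3, replace = TRUE)
    spacing <- round(runif(3, 0.5, 3), 2)
    vent <- array(runif(prod(shape)) < 0.02, shape)
    if (!any(vent)) vent[1, 1, 1] <- TRUE
    tpl <- template_space(shape, spacing,
                          brain_mask = array(TRUE, shape),
                          ventricle_mask = vent)
    dm <- distance_transform(tpl)
    expect_equal(dm$values, brute_distance(vent, spacing), tolerance = 1e-9)
    # invariants: nonnegative, zero exactly on the ventricle
    expect_true(all(dm$values >= 0))
    expect_identical(unname(dm$values == 0), unname(vent))
  }
})

test_that("distance maps are 1-Lipschitz between adjacent voxels", {
  tpl <- small_template(c(20, 20, 20), c(1, 1.5, 2.5))
  dm <- distance_transform(tpl)
  d <- dim(dm$values)
  for (axis in 1:3) {
    step <- tpl$spacing[axis]
    idx_lo <- lapply(d, seq_len); idx_hi <- idx_lo
    idx_lo[[axis]] <- 1:(d[axis] - 1); idx_hi[[axis]] <- 2:d[axis]
    diffs <- abs(dm$values[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]] -
                   dm$values[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]])
    expect_lte(max(diffs), step + 1e-9)
  }
})

test_that("per-subject SVZ distance averages the transform over the mask", {
  tpl <- make_point_template()
  dm <- distance_transform(tpl)

  # mask entirely inside the ventricle: distance 0
  inside <- array(FALSE, tpl$shape); inside[6, 6, 6] <- TRUE
  r0 <- subject_record("in", "proneural", inside, filled = TRUE)
  expect_equal(svz_distance(r0, dm), 0)

  # two voxels at 2 mm and 4 mm: mean 3 mm
  two <- array(FALSE, tpl$shape); two[6, 6, 8] <- TRUE; two[6, 6, 10] <- TRUE
  r2 <- subject_record("two", "neural", two, filled = TRUE)
  expect_equal(svz_distance(r2, dm), 3)

  # random tumor equals the brute-force average
  tpl2 <- small_template(c(20, 20, 20))
  dm2 <- distance_transform(tpl2)
  set.seed(3)
  m <- sample_tumor(tpl2, "classical", cohort_config())
  brute <- brute_distance(tpl2$ventricle_mask, tpl2$spacing)
  expect_equal(
    svz_distance(subject_record("r", "classical", m, filled = TRUE), dm2),
    mean(brute[m]), tolerance = 1e-9
  )
})

test_that("shifting a tumor away from a flat ventricle wall adds one spacing", {
  shape <- c(16, 16, 16)
  vent <- array(FALSE, shape); vent[1, , ] <- TRUE  # planar wall at i = 1
  tpl <- template_space(shape, c(2, 2, 2),
                        brain_mask = array(TRUE, shape),
                        ventricle_mask = vent)
  dm <- distance_transform(tpl)
  m1 <- array(FALSE, shape); m1[5:7, 6:8, 6:8] <- TRUE
  m2 <- array(FALSE, shape); m2[6:8, 6:8, 6:8] <- TRUE  # one voxel farther
  d1 <- svz_distance(subject_record("a", "neural", m1, filled = TRUE), dm)
  d2 <- svz_distance(subject_record("b", "neural", m2, filled = TRUE), dm)
  expect_equal(d2 - d1, 2)
})

test_that("pooled t-test matches the hand computation and the beta-CDF oracle", {
  tab <- data.frame(
    subject_id = sprintf("s%d", 1:6),
    subtype = rep(c("proneural", "classical"), each = 3),
    svz_distance_mm = c(1, 2, 3, 4, 5, 6),
    ce_voxels = rep(10L, 6)
  )
  cmp <- compare_groups(tab, "proneural", "classical")
  # pooled variance 1, SE = sqrt(2/3), t = -3 / sqrt(2/3)
  expect_equal(cmp$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(cmp$degrees_of_freedom, 4)
  expect_equal(cmp$p_value, beta_t_pvalue(cmp$t_statistic, 4),
               tolerance = 1e-9)
  expect_equal(cmp$mean_a, 2); expect_equal(cmp$mean_b, 5)
  expect_equal(cmp$median_a, 2); expect_equal(cmp$median_b, 5)

  # degenerate input: identical constant groups
  tab0 <- tab; tab0$svz_distance_mm <- rep(3, 6)
  expect_error(compare_groups(tab0, "proneural", "classical"),
               "zero pooled variance")
  expect_error(compare_groups(tab[c(1, 4, 5), ], "proneural", "classical"),
               ">= 2 subjects")

  # Welch flag switches the df away from n1 + n2 - 2
  tabw <- tab; tabw$svz_distance_mm <- c(1, 2, 3, 10, 30, 50)
  w <- compare_groups(tabw, "proneural", "classical", welch = TRUE)
  expect_lt(w$degrees_of_freedom, 4)
})

test_that("type-I error of the group comparison is calibrated", {
  set.seed(61)
  rej <- vapply(1:1000, function(i) {
    x <- rnorm(10, 10, 3); y <- rnorm(12, 10, 3)
    tab <- data.frame(
      subject_id = sprintf("s%d", 1:22),
      subtype = rep(c("neural", "mesenchymal"), c(10, 12)),
      svz_distance_mm = c(x, y), ce_voxels = 1L
    )
    compare_groups(tab, "neural", "mesenchymal")$p_value < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), 3 * se + 0.005)
})

test_that("the standard contrast report covers the four pairs plus combined", {
  tpl <- small_template(c(32, 32, 32))
  cfg <- cohort_config(
    n_per_subtype = c(proneural = 5, neural = 5, classical = 5,
                      mesenchymal = 5),
    seed = 77
  )
  co <- make_cohort(tpl, cfg)
  tab <- svz_distance_table(co, tpl)
  expect_identical(nrow(tab), 20L)
  expect_true(all(tab$svz_distance_mm >= 0))
  rep <- svz_group_comparisons(tab)
  expect_identical(nrow(rep), 5L)
  expect_identical(rep$group_a[5], "proneural+neural")
  expect_identical(rep$group_b[5], "classical+mesenchymal")
  # configured geometry: near subtypes closer than far subtypes
  expect_lt(rep$mean_a[5], rep$mean_b[5])
})
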