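#' Write a 3-D array as NIfTI with the template affine
#'
#' @param x Numeric or logical 3-D array on the template grid.
#' @param template A [template_space()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(x, template, path) {
  arr <- if (is.logical(x)) array(as.integer(x), dim(x)) else x
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(template$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  list(array = array(as.numeric(img), dim(img)[1:3]), affine = aff)
}

#' Write / read a template space as a directory of NIfTI masks
#'
#' `brain_mask.nii.gz` and `ventricle_mask.nii.gz` with the affine in the
#' sform; spacing is recovered from the affine column norms on read.
#'
#' @param template A [template_space()].
#' @param dir Directory (created if needed).
#' @return `write_template`: `dir` invisibly; `read_template`: a
#'   [template_space()].
#' @export
write_template <- function(template, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti_map(template$brain_mask, template, file.path(dir, "brain_mask.nii.gz"))
  write_nifti_map(template$ventricle_mask, template,
                  file.path(dir, "ventricle_mask.nii.gz"))
  invisible(dir)
}

#' @rdname write_template
#' @export
read_template <- function(dir) {
  brain <- read_nifti_array(file.path(dir, "brain_mask.nii.gz"))
  vent <- read_nifti_array(file.path(dir, "ventricle_mask.nii.gz"))
  if (max(abs(brain$affine - vent$affine)) > 1e-4) {
    stopf("brain and ventricle masks disagree on the affine")
  }
  spacing <- sqrt(colSums(brain$affine[1:3, 1:3]^2))
  template_space(dim(brain$array), spacing, brain$affine,
                 brain$array > 0, vent$array > 0)
}

#' Write a cohort to disk
#'
#' Emits the template masks, one NIfTI mask per subject under `masks/`, and
#' a subject table `subjects.csv` with header `subject_id,subtype,mask_path`
#' (paths relative to `dir`).
#'
#' @param records List of `subject_record`s.
#' @param template A [template_space()].
#' @param dir Output directory.
#' @return Path of the subject table, invisibly.
#' @export
write_cohort <- function(records, template, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_template(template, file.path(dir, "template"))
  rel <- vapply(records, function(r) {
    p <- file.path("masks", paste0(r$subject_id, ".nii.gz"))
    write_nifti_map(r$ce_mask, template, file.path(dir, p))
    p
  }, character(1))
  tab <- data.frame(
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    subtype = vapply(records, function(r) r$subtype, character(1)),
    mask_path = rel, stringsAsFactors = FALSE
  )
  out <- file.path(dir, "subjects.csv")
  utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read a subject table and its masks
#'
#' Expects a CSV with header `subject_id,subtype,mask_path` (paths relative
#' to the table's directory, or absolute). Masks are binarized at > 0 and
#' validated against the template grid: shape must match and affine elements
#' must agree within 1e-4. Subtype strings are matched case-insensitively;
#' unrecognized labels are rejected with their row number.
#'
#' @param table_path Path to the CSV.
#' @param template A [template_space()].
#' @return List of `subject_record`s (not yet filled).
#' @export
read_subjects <- function(table_path, template) {
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "subtype", "mask_path")
  if (!all(need %in% names(tab))) {
    stopf("subject table must have columns %s", paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(table_path))
  lapply(seq_len(nrow(tab)), function(i) {
    st <- tryCatch(match_subtype(tab$subtype[i]),
                   error = function(e) {
                     stopf("row %d: %s", i, conditionMessage(e))
                   })
    p <- tab$mask_path[i]
    if (!file.exists(p)) p <- file.path(base, tab$mask_path[i])
    if (!file.exists(p)) stopf("row %d: mask file not found: %s", i,
                               tab$mask_path[i])
    nii <- read_nifti_array(p)
    if (!all(dim(nii$array) == template$shape)) {
      stopf("mask %s: grid shape (%s) does not match template (%s)", p,
            paste(dim(nii$array), collapse = "x"),
            paste(template$shape, collapse = "x"))
    }
    if (max(abs(nii$affine - template$affine)) > 1e-4) {
      stopf("mask %s: affine differs from the template affine by more than 1e-4", p)
    }
    subject_record(tab$subject_id[i], st, nii$array > 0, filled = FALSE)
  })
}

#' Pipeline run configuration
#'
#' All knobs of [run_pipeline()] in one serializable object. Either point
#' `template_dir`/`subjects_csv` at data on disk, or leave them `NULL` to
#' simulate a synthetic cohort from `cohort` (a [cohort_config()]).
#'
#' @param template_dir Directory from [write_template()], or `NULL`.
#' @param subjects_csv Subject table path, or `NULL`.
#' @param out_dir Output directory.
#' @param band_mm Periventricular band width, mm.
#' @param sphere_radius_mm Centroid sphere radius, mm.
#' @param voxel_alpha,cluster_alpha Voxel- and cluster-level thresholds.
#' @param n_permutations Label permutations for cluster correction.
#' @param seed Master seed: the cohort (when simulated) and each subtype's
#'   permutation stream are derived from it.
#' @param welch Use Welch instead of pooled t-tests.
#' @param mass_mode `"mass"` or `"presence"` for
#'   [periventricular_fraction()].
#' @param template_shape,template_spacing Synthetic template geometry used
#'   when simulating.
#' @param cohort A [cohort_config()] used when simulating (its seed is
#'   overridden by `seed`).
#' @return A `run_config` list.
#' @export
run_config <- function(template_dir = NULL, subjects_csv = NULL,
                       out_dir = "svzmap-out",
                       band_mm = 10, sphere_radius_mm = 15,
                       voxel_alpha = 0.05, cluster_alpha = 0.05,
                       n_permutations = 1000L, seed = 42L,
                       welch = FALSE, mass_mode = "mass",
                       template_shape = c(64, 64, 64),
                       template_spacing = c(2, 2, 2),
                       cohort = cohort_config()) {
  stopifnot(band_mm >= 0, sphere_radius_mm > 0,
            voxel_alpha > 0, voxel_alpha < 1,
            cluster_alpha > 0, cluster_alpha <= 1,
            n_permutations >= 1)
  structure(
    list(template_dir = template_dir, subjects_csv = subjects_csv,
         out_dir = out_dir, band_mm = band_mm,
         sphere_radius_mm = sphere_radius_mm,
         voxel_alpha = voxel_alpha, cluster_alpha = cluster_alpha,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed),
         welch = isTRUE(welch), mass_mode = mass_mode,
         template_shape = as.integer(template_shape),
         template_spacing = as.numeric(template_spacing),
         cohort = cohort),
    class = "run_config"
  )
}

#' Save / load a run configuration (YAML or JSON, by extension)
#'
#' Round-trips exactly: `read_run_config(write_run_config(cfg, p))` equals
#' `cfg`.
#'
#' @param config A [run_config()].
#' @param path `.yaml`/`.yml` or `.json` file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   [run_config()].
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- lapply(unclass(x$cohort), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ch <- x$cohort
  cohort <- cohort_config(
    n_per_subtype = unlist(ch$n_per_subtype),
    center_distance_mean = unlist(ch$center_distance_mean),
    center_distance_sd = unlist(ch$center_distance_sd),
    tumor_radius_range = unlist(ch$tumor_radius_range),
    laterality_bias = unlist(ch$laterality_bias),
    seed = ch$seed, max_retries = ch$max_retries
  )
  run_config(
    template_dir = x$template_dir, subjects_csv = x$subjects_csv,
    out_dir = x$out_dir, band_mm = x$band_mm,
    sphere_radius_mm = x$sphere_radius_mm, voxel_alpha = x$voxel_alpha,
    cluster_alpha = x$cluster_alpha, n_permutations = x$n_permutations,
    seed = x$seed, welch = x$welch, mass_mode = x$mass_mode,
    template_shape = x$template_shape, template_spacing = x$template_spacing,
    cohort = cohort
  )
}
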