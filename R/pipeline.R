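pipeline_log <- function(con, quiet, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!is.null(con)) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
               con)
  }
  if (!quiet) message(msg)
  invisible(NULL)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[stage %s] %s", name, conditionMessage(e))
  })
}

#' Run the full spatial-localization pipeline
#'
#' Executes every stage in order: load (or simulate) the cohort, fill the CE
#' masks, build the total, per-subtype, and centroid density maps, compute
#' periventricular enrichment fractions, run the per-subtype voxel-wise
#' Fisher tests with permutation cluster correction, compute the SVZ
#' distance table, and run the standard group comparisons. All artifacts are
#' written under `config$out_dir` (NIfTI maps, CSV tables, a machine-readable
#' `summary.json`, and a timestamped `log.txt`). The summary contains no
#' timestamps, so two runs with the same config and seed produce
#' byte-identical `summary.json` files.
#'
#' Degenerate cohorts degrade gracefully: with fewer than two subtype groups
#' the voxel-wise tests are skipped with a logged warning, and group
#' comparisons whose groups have fewer than two subjects are omitted.
#'
#' @param config A [run_config()].
#' @param quiet Suppress console progress messages.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out, "log.txt"), open = "wt")
  on.exit(close(logf), add = TRUE)
  log <- function(...) pipeline_log(logf, quiet, ...)
  t0 <- proc.time()[["elapsed"]]
  log("svzmap %s | seed %d | n_permutations %d",
      as.character(utils::packageVersion("svzmap")), config$seed,
      config$n_permutations)

  # --- stage: inputs -------------------------------------------------------
  simulated <- is.null(config$subjects_csv)
  inputs <- run_stage("inputs", {
    if (simulated) {
      template <- make_template(config$template_shape, config$template_spacing)
      ch <- config$cohort
      ch$seed <- config$seed
      records <- make_cohort(template, ch)
      log("simulated cohort: %d subjects on a %s grid", length(records),
          paste(template$shape, collapse = "x"))
      list(template = template, records = records)
    } else {
      template <- read_template(config$template_dir)
      records <- read_subjects(config$subjects_csv, template)
      log("loaded cohort: %d subjects from %s", length(records),
          config$subjects_csv)
      list(template = template, records = records)
    }
  })
  template <- inputs$template
  records <- inputs$records
  subtype_counts <- table(factor(
    vapply(records, function(r) r$subtype, character(1)), levels = SUBTYPES
  ))

  # --- stage: fill ---------------------------------------------------------
  records <- run_stage("fill", fill_records(records))
  log("filled %d CE masks", length(records))

  # --- stage: density ------------------------------------------------------
  dmap_dist <- run_stage("distance", distance_transform(template))
  dens <- run_stage("density", {
    masks <- lapply(records, function(r) r$ce_mask)
    total <- density_map(masks, "all")
    by_subtype <- list()
    for (st in SUBTYPES) {
      sel <- vapply(records, function(r) r$subtype == st, logical(1))
      if (any(sel)) by_subtype[[st]] <- density_map(masks[sel], st)
    }
    cent <- centroid_density_map(records, template, config$sphere_radius_mm,
                                 "all-centroids")
    list(total = total, by_subtype = by_subtype, centroid = cent)
  })
  log("density maps: total + %d subtype map(s) + centroid map",
      length(dens$by_subtype))

  # --- stage: periventricular ---------------------------------------------
  pv <- run_stage("periventricular", {
    groups <- c(list(all = dens$total, centroids = dens$centroid),
                dens$by_subtype)
    do.call(rbind, lapply(names(groups), function(g) {
      fr <- periventricular_fraction(groups[[g]], template, config$band_mm,
                                     distance = dmap_dist,
                                     mode = config$mass_mode)
      data.frame(group = g, mass_fraction = fr$mass_fraction,
                 volume_fraction = fr$volume_fraction,
                 band_mm = fr$band_mm, stringsAsFactors = FALSE)
    }))
  })
  log("periventricular band <= %g mm: %.1f%% of density mass in %.1f%% of brain",
      config$band_mm, 100 * pv$mass_fraction[pv$group == "all"],
      100 * pv$volume_fraction[pv$group == "all"])

  # --- stage: subtype clusters --------------------------------------------
  known <- setdiff(names(subtype_counts)[subtype_counts > 0], "unknown")
  clusters <- list()
  if (length(known) < 2L) {
    warning("only one subtype group present; voxel-wise subtype tests skipped")
    log("WARNING: voxel-wise subtype tests skipped (single subtype group)")
  } else {
    clusters <- run_stage("clusters", {
      out_c <- list()
      for (st in known) {
        pmap <- voxelwise_subtype_test(records, st, template)
        cr <- cluster_filter(pmap, records, st, template,
                             voxel_alpha = config$voxel_alpha,
                             cluster_alpha = config$cluster_alpha,
                             n_permutations = config$n_permutations,
                             seed = config$seed + match(st, SUBTYPES))
        out_c[[st]] <- cr
        log("subtype %s: %d cluster(s), %d retained", st,
            length(cr$cluster_sizes), sum(cr$retained))
      }
      out_c
    })
  }

  # --- stage: svz ----------------------------------------------------------
  svz_tab <- run_stage("svz", svz_distance_table(records, template, dmap_dist))
  comparisons <- run_stage("compare", {
    ok <- list()
    contrasts <- list(
      list(a = "proneural", b = "classical"),
      list(a = "proneural", b = "mesenchymal"),
      list(a = "neural", b = "classical"),
      list(a = "neural", b = "mesenchymal"),
      list(a = c("proneural", "neural"), b = c("classical", "mesenchymal"))
    )
    for (ct in contrasts) {
      res <- tryCatch(compare_groups(svz_tab, ct$a, ct$b, welch = config$welch),
                      error = function(e) {
                        log("WARNING: contrast %s vs %s skipped: %s",
                            paste(ct$a, collapse = "+"),
                            paste(ct$b, collapse = "+"), conditionMessage(e))
                        NULL
                      })
      if (!is.null(res)) ok[[length(ok) + 1L]] <- res
    }
    if (length(ok)) do.call(rbind, ok) else NULL
  })

  # --- stage: write --------------------------------------------------------
  run_stage("write", {
    write_template(template, file.path(out, "template"))
    write_nifti_map(dens$total$probability, template,
                    file.path(out, "density_all.nii.gz"))
    write_nifti_map(dens$centroid$probability, template,
                    file.path(out, "density_centroids.nii.gz"))
    for (st in names(dens$by_subtype)) {
      write_nifti_map(dens$by_subtype[[st]]$probability, template,
                      file.path(out, sprintf("density_%s.nii.gz", st)))
    }
    for (st in names(clusters)) {
      write_nifti_map(clusters[[st]]$p_map, template,
                      file.path(out, sprintf("pmap_%s.nii.gz", st)))
      write_nifti_map(clusters[[st]]$retained_labels, template,
                      file.path(out, sprintf("clusters_%s.nii.gz", st)))
      utils::write.csv(cluster_table(clusters[[st]]),
                       file.path(out, sprintf("clusters_%s.csv", st)),
                       row.names = FALSE)
    }
    utils::write.csv(pv, file.path(out, "periventricular.csv"),
                     row.names = FALSE)
    utils::write.csv(svz_tab, file.path(out, "svz_distance.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(out, "svz_comparisons.csv"),
                       row.names = FALSE)
    }
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("svzmap")),
    seed = config$seed,
    parameters = list(
      band_mm = config$band_mm, sphere_radius_mm = config$sphere_radius_mm,
      voxel_alpha = config$voxel_alpha, cluster_alpha = config$cluster_alpha,
      n_permutations = config$n_permutations, welch = config$welch,
      mass_mode = config$mass_mode
    ),
    n_subjects = length(records),
    n_per_subtype = as.list(subtype_counts),
    periventricular = pv,
    clusters = lapply(clusters, function(cr) {
      list(n_clusters = length(cr$cluster_sizes),
           n_retained = sum(cr$retained),
           sizes = cr$cluster_sizes, cluster_p = cr$cluster_p,
           retained = cr$retained)
    }),
    svz_distance = svz_tab,
    comparisons = comparisons
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  log("done in %.1f s", proc.time()[["elapsed"]] - t0)
  invisible(summary)
}
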