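#!/usr/bin/env Rscript
# Stage 3 — where is each subtype over-represented?
#
# Voxel-wise two-tailed Fisher's exact test of each subtype against the
# rest (unknowns excluded), then permutation-based cluster-level correction:
# only 26-connected suprathreshold clusters larger than chance (label
# permutation null of the maximum cluster size, p <= 0.05) are retained.

suppressPackageStartupMessages(library(svzmap))

out <- "results/clusters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- read_run_config("results/cohort/run_config.yaml")$seed

template <- read_template("results/cohort/template")
records <- fill_records(read_subjects("results/cohort/subjects.csv", template))
subtypes <- vapply(records, function(r) r$subtype, character(1))
present <- setdiff(intersect(SUBTYPES, unique(subtypes)), "unknown")

for (st in present) {
  pmap <- voxelwise_subtype_test(records, st, template)
  cr <- cluster_filter(pmap, records, st, template,
                       voxel_alpha = 0.05, cluster_alpha = 0.05,
                       n_permutations = 1000, seed = seed + match(st, SUBTYPES))
  write_nifti_map(cr$p_map, template, file.path(out, sprintf("pmap_%s.nii.gz", st)))
  write_nifti_map(cr$retained_labels, template,
                  file.path(out, sprintf("clusters_%s.nii.gz", st)))
  write.csv(cluster_table(cr), file.path(out, sprintf("clusters_%s.csv", st)),
            row.names = FALSE)
  message(sprintf("%-12s %d suprathreshold cluster(s), %d retained (largest %s voxels)",
                  st, length(cr$cluster_sizes), sum(cr$retained),
                  if (length(cr$cluster_sizes)) max(cr$cluster_sizes) else "0"))
}
message("wrote p-maps, cluster maps and tables to ", out)
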