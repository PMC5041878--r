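#!/usr/bin/env Rscript
# Stage 2 — tumor density maps and periventricular enrichment.
#
# Layers the filled CE masks into cohort-level, per-subtype and
# centroid-sphere density maps, then asks how much of the density mass lies
# within 10 mm of the lateral ventricles versus how much of the brain that
# band occupies. Maps go to results/density/ as NIfTI, fractions to CSV.

suppressPackageStartupMessages(library(svzmap))

out <- "results/density"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

template <- read_template("results/cohort/template")
records <- fill_records(read_subjects("results/cohort/subjects.csv", template))
dist <- distance_transform(template)

masks <- lapply(records, function(r) r$ce_mask)
subtypes <- vapply(records, function(r) r$subtype, character(1))

total <- density_map(masks, "all")
cent <- centroid_density_map(records, template, radius_mm = 15)
write_nifti_map(total$probability, template, file.path(out, "density_all.nii.gz"))
write_nifti_map(cent$probability, template,
                file.path(out, "density_centroids.nii.gz"))

groups <- list(all = total, centroids = cent)
for (st in intersect(SUBTYPES, unique(subtypes))) {
  dm <- density_map(masks[subtypes == st], st)
  groups[[st]] <- dm
  write_nifti_map(dm$probability, template,
                  file.path(out, sprintf("density_%s.nii.gz", st)))
}

fractions <- do.call(rbind, lapply(names(groups), function(g) {
  fr <- periventricular_fraction(groups[[g]], template, band_mm = 10,
                                 distance = dist)
  data.frame(group = g, mass_fraction = fr$mass_fraction,
             volume_fraction = fr$volume_fraction, band_mm = fr$band_mm)
}))
write.csv(fractions, file.path(out, "periventricular.csv"), row.names = FALSE)

fa <- fractions[fractions$group == "all", ]
message(sprintf(paste0("%.1f%% of total CE density mass lies within 10 mm of ",
                       "the ventricles, a band holding %.1f%% of brain volume"),
                100 * fa$mass_fraction, 100 * fa$volume_fraction))
message("wrote density maps and fractions to ", out)
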