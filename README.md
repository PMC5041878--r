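# svzmap

Spatial localization analysis of glioblastoma molecular subtypes relative to
the subventricular zone (SVZ), from binary contrast-enhancing (CE) tumor
masks registered to a shared template space.

## The scientific question

Glioblastoma comes in molecular subtypes (proneural, neural, classical,
mesenchymal, plus the G-CIMP methylator phenotype). If subtypes arise from
different cells of origin — neural stem cells live in the SVZ, adjacent to
the lateral ventricles, while progenitor populations sit farther out — then
subtypes should occupy different regions of the brain and differ in their
proximity to the ventricles. Given per-subject binary CE masks in one
template space and subtype labels, `svzmap` quantifies exactly that:

1. **Density maps.** Each subject's CE mask is hole-filled (the enhancing
   rim encloses a necrotic core) and layered: at voxel $v$ the density is
   $P(v) = \tfrac{1}{N}\sum_{i=1}^{N} M_i(v)$, the fraction of subjects
   whose filled mask covers $v$. Centroid density maps replace each mask by
   a 15-mm sphere at its center of mass.
2. **Periventricular enrichment.** With $d(v)$ the Euclidean distance (mm)
   from voxel $v$ to the nearest lateral-ventricle voxel, the band
   $B = \{v : d(v) \le 10\}$ is compared on two scales: the share of total
   density mass inside $B$ versus the share of brain volume that $B$
   occupies.
3. **Subtype-specific regions.** At every voxel, a two-tailed Fisher's
   exact test on the 2×2 table (subtype-with-tumor, subtype-without,
   others-with, others-without) contrasts each subtype against the rest.
   Suprathreshold voxels ($p < 0.05$) are grouped into 26-connected
   clusters, and a cluster is kept only if its size beats the permutation
   null: subtype labels are shuffled across subjects, the voxel-wise test is
   recomputed, and the maximum null cluster size is recorded
   ($p_\text{cluster} = \frac{1 + \#\{\text{null max} \ge s\}}{n_\text{perm} + 1} \le 0.05$).
4. **SVZ distance.** Per subject, the mean of $d(v)$ over all filled-CE
   voxels; subtype groups are compared with two-sample pooled t-tests
   (Welch optional) — each of proneural/neural versus each of
   classical/mesenchymal, plus the combined near-vs-far contrast.

A synthetic-data module generates a template (ellipsoidal brain, paired
lateral ventricles) and cohorts of solid tumors whose center-to-ventricle
distances follow subtype-specific truncated normal distributions, so the
whole pipeline runs and is tested without any external imaging data. Real
data in NIfTI format drops into the same interfaces (`read_template()`,
`read_subjects()`).

## Worked example

The numbered scripts under `analysis/` run the full study on the default
synthetic cohort (60 subjects, 64³ grid at 2 mm):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_density_maps.R
Rscript analysis/03_subtype_clusters.R
Rscript analysis/04_svz_distance.R
```

Stage 4 prints (seed 42):

```
median SVZ distance (mm) by subtype:
  classical      19.0
  gcimp           8.3
  mesenchymal    21.4
  neural         12.7
  proneural      12.1
  ...
  proneural+neural vs classical+mesenchymal: mean 12.3 vs 21.0 mm, t = -9.52, p = 5.51e-13
```

i.e. the generator's planted structure — proneural/neural tumors seeded near
the ventricles, classical/mesenchymal far — is recovered by the SVZ-distance
statistic with a strongly significant combined contrast. Stage 2 reports the
periventricular band occupancy (`19.4% of total CE density mass ... band
holding 18.7% of brain volume` for this seed), and stage 3 writes per-subtype
p-maps and permutation-corrected cluster tables.

The same stages are available as one call:

```r
library(svzmap)
summary <- run_pipeline(run_config(out_dir = "out", seed = 42))
```

which writes all NIfTI maps, CSV tables and a deterministic `summary.json`.

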