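---
title: "Mapping glioblastoma subtype localization relative to the subventricular zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping glioblastoma subtype localization relative to the subventricular zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis model

`svzmap` treats a glioblastoma cohort as a set of binary contrast-enhancing
(CE) masks $M_1, \dots, M_N$ on one template grid, each carrying a molecular
subtype label in {proneural, neural, classical, mesenchymal, gcimp,
unknown}. Three assumptions are baked in and worth stating plainly:

* **Registration has already happened.** Every mask, the brain mask and the
  lateral-ventricle mask live on the same grid with the same voxel-to-world
  affine; the package validates this (shape equality, affine elements within
  1e-4) and refuses mismatched inputs rather than resampling them.
* **The CE rim stands for the whole tumor.** Enhancing segmentations ring a
  necrotic core, so every mask is hole-filled before analysis: the filled
  mask is the complement of the background component(s) reachable from the
  array boundary. Background connectivity is 6 and foreground 26 — the
  standard complementary pair, so a cavity touching the mask only
  diagonally still counts as enclosed.
* **The ventricle voxel set stands for the SVZ.** Distances are measured to
  the nearest ventricle voxel center. For any point outside the mask this
  equals the distance to the ventricular border, which is the quantity of
  interest; voxels inside the lumen get distance 0, on the reasoning that a
  tumor reaching into the ventricle is maximally "at" the SVZ rather than a
  positive distance away from its wall.

### Density and enrichment

Density maps are overlap counts divided by group size, so values are exact
rationals in $[0,1]$ and counts are additive across disjoint groups — both
properties are tested. Centroid density maps summarize tumor *placement*
separately from tumor *extent*: a 15-mm-radius sphere (voxel-center
membership, closed ball) at each filled mask's unweighted center of mass,
layered the same way. Periventricular enrichment compares two fractions for
a band of width $b$ (default 10 mm): the probability-weighted share of
density mass at distance $\le b$ from the ventricles, and the share of
brain volume the band occupies. Density mass is the default reading of
"how much tumor sits near the ventricles"; a presence-based variant (share
of distinct tumor-bearing voxels in the band) is available via
`mode = "presence"` since either convention is defensible.

### Voxel-wise subtype inference

At each brain voxel with at least one tumor, the 2×2 table
(subtype-with/without, rest-with/without) is tested with a two-tailed
Fisher's exact test using the point-probability rule: sum the
hypergeometric probabilities of all tables (margins fixed) whose
probability does not exceed the observed table's, with a relative tolerance
of 1e-9 for floating-point ties. This is the dominant two-sided convention
(it matches `stats::fisher.test`, which the test suite uses as an
independent cross-check; the implementation itself enumerates the
hypergeometric support directly so that permutation reruns can be driven
off a margin-indexed lookup). Voxels with no overlap anywhere, and voxels
outside the brain mask, are assigned $p = 1$ so p-maps stay dense and
shape-stable. Subjects labelled `unknown` are excluded from both margins;
`gcimp` is kept as its own group.

Cluster-level correction is the standard family-wise max-statistic
permutation procedure: threshold at `voxel_alpha` (strict $p <$), label
26-connected components, then permute subtype labels across subjects
`n_permutations` times, rerunning the full voxel-wise test each time and
recording the largest suprathreshold cluster. Because the margins of every
voxel's table are invariant under relabelling, the exact p-values for a
permutation are a lookup into the $(n_1 + 1) \times (n_2 + 1)$ table of
Fisher p-values — identical values to per-voxel re-enumeration, computed as
one matrix product per permutation block. Cluster p-values use the add-one
estimator $(1 + \#\{\text{null max} \ge s\}) / (n_\text{perm} + 1)$, which
can never fall below $1/(n_\text{perm}+1)$ and is retained at
`cluster_alpha` ($\le 0.05$ by default, i.e. clusters with more than a 5%
chance of arising by permutation are discarded).

### SVZ distance and group comparisons

The per-subject statistic is the unweighted mean of the ventricular
distance transform over the filled CE voxels. The transform is the exact
Euclidean distance in world mm, computed by the separable lower-envelope
(parabola) algorithm axis by axis with the squared per-axis spacings, which
is exact for anisotropic axis-aligned grids; the test suite verifies
equality with a brute-force minimum-over-ventricle-voxels scan to 1e-9 on
random templates up to 32³. Group contrasts use the pooled two-sample
t-test by default — the classical "Student's t-test" — with Welch's
correction behind `welch = TRUE` for unequal variances. The default report
covers the four pairwise near-vs-far contrasts and the combined
proneural+neural vs classical+mesenchymal comparison, with means and
medians both emitted (distributions of a voxel-averaged distance can be
skewed, so the median is a useful companion summary).

## The synthetic cohort generator

The generator exists so that every downstream stage is testable end to end
with data of known structure. It emulates:

* a template with an ellipsoidal brain (semi-axes 90% of the half field of
  view) and two parallel ellipsoidal lateral ventricles straddling the
  mid-sagittal plane ($x = 0$; negative world $x$ is the left hemisphere);
* per-subtype cohorts of solid spherical tumors (radius uniform in 8–16 mm
  by default), intersected with the brain, whose center-to-ventricle
  distance is drawn from a subtype-specific normal distribution truncated
  to achievable distances by rejection sampling (cap 10,000 tries, then an
  error reporting the achievable range);
* an optional left-hemisphere placement bias per subtype.

Defaults are one fixed choice of realistic study conditions: 60 subjects
split 13/11/14/16/3/3 (proneural/neural/classical/mesenchymal/gcimp/unknown),
matching typical subtype frequencies at roughly one-quarter scale of a
200-odd-patient cohort; distance means 8/10/22/25/8/15 mm with a common 4 mm
standard deviation, encoding the near-ventricle placement of
proneural-like tumors and the more peripheral classical/mesenchymal
distribution; left bias 0.7 for proneural and neural (temporal-lobe
asymmetry), 0.5 elsewhere. Published work motivates the ordering of these
distances but not their values, so the magnitudes are illustrative by
design.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: registration error, segmentation noise,
irregular and multifocal tumor shapes, mass effect and ventricle
deformation, spatially varying cohort coverage, and any intensity
information at all (only binary masks are produced). Tests on synthetic
cohorts validate the machinery (exactness of the geometry, calibration of
the statistics, recovery of planted structure), not clinical conclusions.

One shared seeded stream drives a cohort, consumed in fixed subject order,
so `make_cohort()` is bit-for-bit reproducible from its config seed and
independent of any parallelism; the generator saves and restores the
caller's RNG state.

## Numerical and design choices

* Voxel indices are 0-based in the voxel-to-world affine (the NIfTI sform
  convention); all distances and radii are in world mm, so anisotropic
  spacing is handled throughout.
* Sphere and ellipsoid membership use voxel centers with closed
  inequalities; no partial-volume weighting anywhere.
* Centroids are unweighted voxel-center means of filled masks.
* The hole-filling flood fill propagates frontier masks with vectorized
  array shifts to a fixed point; component labelling does frontier BFS over
  the 26-neighbourhood. Both are exercised against naive queue-based
  oracles.
* Permutation streams, cohort seeds and the pipeline master seed are all
  plain integers; the pipeline derives each subtype's permutation seed as
  `seed + subtype index` so subtype analyses are independent but
  reproducible.
* Degenerate inputs fail loudly with the violated invariant named: empty
  masks, ventricles outside the brain, all-zero density maps, groups with
  fewer than two subjects, zero pooled variance.
* A genuinely open reading in the source method — whether "clusters with a
  >5% probability of occurring by chance were kept" means keep or discard
  such clusters — is resolved the only way consistent with the
  accompanying $p < 0.05$ cluster criterion: clusters are *retained* when
  their permutation p-value is at most 5%.

## Problem sizes used by the test suite

The suite favors many small exact checks over few large ones: oracle
equivalence runs on random grids up to 32³ (distance transform, filling,
spheres) and on all 2×2 tables with margins up to 12 (Fisher enumeration);
calibration simulations use 200 null cohorts of 40 subjects with 200
permutations each (family-wise error of the cluster filter) and 50
replicates of 20-vs-20 cohorts (power and sign of the SVZ contrast, plus a
matched null); the end-to-end determinism check runs the full default
64³/60-subject pipeline twice. These sizes were chosen so the entire suite
exercises every claim at meaningful resolution while staying comfortably
interactive.

## Known limitations

* Distances are straight-line Euclidean; no geodesic or white-matter-
  constrained variant.
* The distance transform assumes an axis-aligned (orthogonal) affine, the
  normal situation for template space; oblique affines are not supported.
* One-vs-rest contrasts only; no omnibus multi-group voxel test, no
  parametric random-field or FDR alternatives to the permutation cluster
  correction.
* Figure-quality rendering is out of scope; maps are written as NIfTI for
  any standard viewer.
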