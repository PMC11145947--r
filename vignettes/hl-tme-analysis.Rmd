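---
title: "Characterizing the Hodgkin lymphoma microenvironment by HLA status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing the Hodgkin lymphoma microenvironment by HLA status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hltme)
```

## The scientific problem

Classic Hodgkin lymphoma (HL) is unusual among cancers: the neoplastic
Hodgkin-Reed-Sternberg cells (HRSCs, identified by CD30) are rare, scattered
cells embedded in an abundant non-neoplastic tumor microenvironment (TME).
HRSCs frequently lose surface expression of HLA class I (assessed via
beta-2-microglobulin) and, less often, HLA class II, which shields them from
CD8+ and CD4+ T-cell recognition respectively. `hltme` implements a complete
analysis of how HLA expression on HRSCs relates to TME composition, using
four data modalities:

1. **Bulk gene expression** (NanoString-like count panels) compared between
   HLA-positive and HLA-negative cases by per-gene logistic regression,
   optionally adjusting for EBV status of the HRSCs.
2. **Multiplexed immunofluorescence cell maps** (QuPath-style cell
   detections) zoned by distance to the nearest HRSC, with phenotype
   composition per zone and paired close-vs-distant comparisons.
3. **Bulk TCR-beta repertoires** summarized by Simpson's clonality and
   compared between HLA groups.
4. **Cohort annotation tables** analyzed by exact contingency-table tests
   (Fisher exact, Pearson chi-square).

The patient-level data this analysis was designed for are not publicly
deposited, so the package ships a synthetic cohort generator that
reproduces the *statistical structure* of each modality. Every pipeline
stage is validated by recovering the generator's known ground truth.

## Spatial zoning model

Each cell map is a set of cell centroids in micrometers with boolean marker
calls. The HRSC reference set is all CD30+ detections. For every other cell
we compute the Euclidean distance to the nearest HRSC and assign:

* **close**: distance <= 28.33 um (inclusive);
* **distant**: distance > 75 um (strict);
* **intermediate**: everything between — excluded from close/distant
  contrasts.

The 28.33 um threshold is honored verbatim from the published image-analysis
convention (it presumably derives from a fixed pixel-scale dilation, about
two lymphocyte diameters); region-of-interest rectangles in published
figures are treated as illustrative — zones here are defined per cell by the
stated radii. Distances are centroid-to-centroid because membrane geometry
is unrecoverable from point detections. The nearest-distance computation is
required to match a brute-force all-pairs oracle *exactly* (no tolerance),
which the test suite enforces on random maps up to 500 cells.

Phenotypes are pure functions of marker calls, organized in a
`phenotype_scheme()`. Two canned schemes mirror the published readouts:
`tme_marker_scheme()` (CD68, CD8, LAG3, FoxP3, PD1 as fractions of all
non-HRSC cells) and `cd8_coexpression_scheme()` (CD8_only = CD8+ lacking
LAG3/FoxP3/PD1, plus CD8_LAG3, CD8_FoxP3, CD8_PD1, CD8_TIM3 as fractions of
all CD8+ cells). Labels need not partition the cells: a CD8+LAG3+PD1+ cell
counts toward both CD8_LAG3 and CD8_PD1. CD30+ cells never receive an
immune label. Because composition fractions use all detections of the
denominator population (not only "nucleated" subsets, which the detection
tables cannot distinguish), fractions are comparable across zones within a
scheme.

Zone contrasts use the classical paired t-test on per-case (close minus
distant) fractions, the convention of the source analyses. Group scoring of
HLA by immunohistochemistry is strict: a case is positive only if *more*
than 50% of HRSCs stain unambiguously (`score_hla_status(0.5)` is `"neg"`).

## Differential expression model

Counts are QC'd, transformed, and tested as follows:

* **Sample QC**: a sample is removed when 50% or fewer of its genes exceed
  the limit of detection (boundary inclusive — a sample with exactly half
  its genes detected is removed).
* **Normalization**: `log2(count + 1)` (pseudocount configurable), then
  centering to mean zero within each sample. Centering absorbs per-sample
  scale factors, which stands in for library-size normalization.
* **Test**: the published convention models HLA status as the *response*:
  for each gene we fit a binomial GLM (logit link) of status (pos = 1) on
  that gene's centered expression, optionally with an EBV indicator as a
  second predictor, and report the two-sided Wald p-value of the gene
  coefficient. The GLM family/link and the Wald (rather than LR or score)
  test are the conventional reading of a logistic "generalized linear
  model" with a binary response; this choice is deliberately recorded here
  because the alternatives differ only in higher-order asymptotics at these
  group sizes.
* **Fold-change**: mean centered-log2 expression in the HLA-negative group
  minus the HLA-positive group, so positive fold-changes mean "up in
  HLA-negative". The 0.6 volcano threshold therefore lives on the log2
  scale. Computing it on centered values (rather than raw log2) only
  changes results through the sample-centering offsets; the group-mean
  difference is otherwise shift-invariant.
* **Volcano classification** uses the raw p-value with the printed
  boundary conventions: `up_in_negative` iff p <= 0.05 and FC > 0.6
  (strict), `down_in_negative` iff p <= 0.05 and FC <= -0.6 (inclusive).
  Benjamini-Hochberg q-values are reported alongside every result.

Genes that reach complete or quasi-separation in the logistic fit are
flagged (`separated`); their Wald p-values are anticonservative in the
Hauck-Donner sense (typically near 1) and should be interpreted with care
— they are retained, not dropped, so that gene lists keep a stable length.

## Clonality

Simpson's index of a repertoire is the sum of squared productive clone
frequencies; following the Adaptive Biotechnologies convention, *Simpson's
clonality* is its square root, ranging from 1/sqrt(richness) (perfectly
even) to 1 (monoclonal). Both are reported, the square root being primary;
the unrooted index is included because the two conventions are easily
confused between platforms. Repertoire tables are renormalized on load and
zero-count clones dropped. Group comparisons use an unpaired two-sided
t-test on clonality.

## Association statistics

`fisher_exact_2x2()` implements the two-sided Fisher exact test by the
point-probability rule: with margins fixed, it sums the hypergeometric
probabilities of all tables whose probability does not exceed the observed
table's (relative tie tolerance 1e-7). The pmf is evaluated in log space so
that totals near 100 cases are handled without overflow. This is the
convention of mainstream statistical software and reproduces the published
cohort values: on the HLA-I by EBV table (5/6 vs 7/79) it gives p = 0.0038,
and on the HLA-I by HLA-II table (7/4 vs 46/39) p = 0.7494. The
`chi_square_rxc()` test is the uncorrected Pearson statistic (no Yates
correction, which is undefined for df > 1 anyway); on the 2x3 HLA-I by
subtype table ([3,3,2] vs [66,12,1]) it gives p = 0.0004. The published
table also prints 0.0058 and 0.002 for these rows, which match neither of
the stated test methods on the printed counts; this package reproduces the
values implied by the stated methods and does not attempt to match the
others. In that subtype table, one garbled published cell was resolved to
count 1, the only value consistent with the printed column totals.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated:

* **Annotation**: HLA-I+ prevalence 11/97 and HLA-II+ prevalence 53/98
  (the cohort proportions typical of adult central-European HL); EBV+
  conditional on HLA-I at 5/11 vs 7/86 (odds ratio ~9.4); subtype mixes
  (nodular sclerosis / mixed cellularity / other) of roughly 37/37/25% in
  HLA-I+ and 84/15/1% in HLA-I- cases; small non-evaluable ("na") rates per
  variable to exercise case-wise exclusion.
* **Cell maps**: HRSCs are a homogeneous Poisson process (default
  30/mm^2, halved in HLA-I+ cases to emulate their lower tumor-cell
  content); immune cells of nine phenotype classes are inhomogeneous
  Poisson processes realized by thinning. Within 28.33 um of an HRSC a
  class's intensity is baseline times its enrichment factor, beyond 75 um
  it is baseline, with *linear interpolation between* — the analysis
  defines only the two zones, and the ramp avoids manufacturing a
  discontinuity at an arbitrary radius. Default densities (6000 immune
  cells/mm^2) are of the order of cell-detection densities in lymph-node
  tissue sections. Default enrichments reflect the qualitative published
  pattern (macrophages and checkpoint-positive T cells enriched near
  HRSCs, plain CD8 cells slightly depleted); the source figures print no
  numeric effect sizes, so these defaults are illustrative, not
  calibrated. HRSCs carry lognormal TARC intensities (lower mean in
  HLA-I+, intermediate in EBV+ cases) and gamma-distributed areas.
* **Expression**: negative-binomial counts (size 10 — NanoString counts
  are overdispersed) with log2-scale group shifts expressed directly on
  the fold-change scale (a +1.2 shift for CCL17 means 1.2 log2 units
  higher in HLA-negative cases). Default signature genes mirror the
  published direction of effect: HRSC cytokines (CCL17/TARC, CCL22, IL13)
  and TNFRSF8/CD30 up in HLA-negative disease, cytotoxic/B-cell genes
  (CD8B, MS4A1, CD19) up in HLA-positive disease, with small EBV effects
  on the chemokines to exercise the confounder adjustment.
* **Repertoires**: symmetric Dirichlet clone frequencies; the default
  (2000 clones, concentration 0.05) gives clonality near 0.1 — the highly
  polyclonal regime reported for the HL microenvironment.

Reproducibility is structural: one master seed derives per-case child
seeds (a fixed-multiplier integer map), and every per-case quantity —
annotation row, cell map, expression column, repertoire — depends only on
its own child seed, so *extending a cohort never changes the cases already
drawn*, a property the tests assert with `identical()`.

What the generator does **not** emulate: staining noise and segmentation
errors, spatial clustering of HRSCs (they are scattered uniformly), tissue
architecture (follicles, sclerosis bands), cross-gene correlation, and
V(D)J sequence structure. Passing tests therefore demonstrate that the
pipeline recovers the *generating* statistical structure, not that the
biological effect sizes in real tissue are as simulated.

## Validation experiments and problem sizes

The package validates itself through four experiment functions, also used
by `scripts/acceptance.R`:

* `spatial_enrichment_recovery(f)` — maps with only CD8_LAG3 enriched by
  factor f; the close/distant fraction ratio (counts pooled over 20 seeds,
  ~10,000 cells per 1.44 mm^2 map) must recover f. The estimate is biased
  a few percent below f because the enriched class inflates the close-zone
  denominator (at a 4% baseline share, the expected ratio at f = 3 is
  3/1.08 ≈ 2.78); the 15% recovery band absorbs this known, quantified
  bias rather than hiding it with a bias-corrected estimator.
* `spatial_null_calibration()` — 40 null cohorts of 8 cases: the paired
  close-vs-distant t-test must reject at the nominal 5% rate within
  binomial 99% bounds.
* `de_null_calibration()` — 20 null matrices of 200 genes at 40 + 40
  samples (4000 independent null genes): the per-gene logistic Wald test's
  type-I error must sit within the binomial 99% band around 0.05.
* `de_shift_recovery(1.0)` — a +1.0 log2 gene at 40 + 40 samples must be
  volcano-classified in >= 90% of 20 seeds with its fold-change recovered
  within +-0.2.

These sizes were chosen so each experiment's Monte-Carlo error is small
against the acceptance band while the whole suite stays interactive.

## A small end-to-end run

```{r pipeline, eval = FALSE}
cfg <- default_run_config(seed = 1, n_cases = 97)
report <- run_pipeline(cfg)
report
plot_volcano(report$de)
```

`run_pipeline()` simulates (or loads) the cohort, runs QC, both DE analyses,
spatial composition with both schemes, clonality, and the three association
tests, and logs every excluded sample with its reason — mirroring the
explicit sample-removal accounting of the source analyses. With an
`output_dir` set, each stage table is written as TSV as it completes, plus
a volcano plot.

## Known limitations

* The Wald p-value is unreliable under separation (flagged, see above);
  a conditional-likelihood or Firth fallback is a possible extension.
* `cd30_area_fraction()` sums detection areas; overlapping HRSC areas are
  double-counted, as they are in detection-table exports.
* The intermediate zone (28.33–75 um) is computed and reported but not
  tested by `compare_zones()` defaults, matching the published design.
* Fisher's exact test is implemented for 2x2 tables only; r x c exact
  tests (Freeman-Halton) are out of scope, use the chi-square instead.
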