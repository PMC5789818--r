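---
title: "mitopla: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitopla: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`mitopla` implements the computational side of a mitotic interactome
screen built around two assays: automated *in situ* proximity ligation
(is-PLA) microscopy, which renders pairwise protein interactions as
discrete fluorescent puncta in intact cells, and affinity-purification
mass spectrometry (AP-MS) of a bait protein (importin beta-1) versus a
non-specific IgG control. The package covers three stages:

1. **Simulation** — a ground-truthed generator of multi-field, multi-channel
   z-stack acquisitions and of MaxQuant-style proteinGroups fixture tables.
2. **Imaging analysis** — maximum-intensity projection, background
   subtraction, intensity/size/circularity segmentation, interphase vs
   mitotic classification, per-cell PLA sum-intensity quantification,
   ground-truth evaluation, and a Mann-Whitney comparison of control vs
   importazole-treated conditions.
3. **Interactome post-processing** — confidence filtering of protein
   groups, bait-vs-IgG enrichment testing with missing-value imputation,
   and cross-tabulation of hits against mitotic phenotype annotations.

Because raw screen data of this kind are rarely deposited, the simulator is
a first-class module: it defines the study conditions under which the
imaging pipeline is benchmarked, and every pipeline claim the test suite
makes is a claim about recovery of the simulator's known ground truth.

## The simulated acquisition

An acquisition is a grid of xy fields (60 by default), each recorded as 10
z planes in three channels: DAPI (DNA), FITC (alpha-tubulin, or a
phospho-histone H3 marker), TRITC (PLA amplification products). Images are
16-bit, 0.325 um/px, emulating a 40x widefield objective with a cooled
monochrome CCD.

**Cells.** Each field holds a small number of non-overlapping cells placed
by rejection sampling with a minimum centre separation (an explicit
placement error is raised if the field cannot host the request — the
generator never silently truncates). A cell is mitotic with probability
`mitotic_fraction`: around 0.06 for an asynchronous culture, 0.5 or more
for a synchronized, mitosis-enriched one.

**The DAPI contrast.** Interphase nuclei are near-round ellipses (axis
ratio 0.85–1.0) of moderate peak intensity; mitotic chromosome masses are
unions of 2–4 elongated ellipse lobes (axis ratio 0.35–0.55, lobes spread
along the metaphase-plate axis), brighter (chromatin condensation) and
distinctly non-round. Peak intensities are lognormal, meanlog `log(8000)`
vs `log(20000)` with sdlog 0.12 for both classes. These are free
parameters — no quantitative intensity statistics exist for the original
acquisitions — chosen once so that the two populations are what the
segmentation design assumes: separable by a single intensity/circularity
threshold pair with essentially no overlap. The tests verify that property
on the generator's ground truth before any imaging is involved.

**Spindles.** Each mitotic cell carries one bright elliptical tubulin
spindle (axis ratio 0.45–0.6) centred on the chromosome mass with its long
axis perpendicular to the plate; interphase cells contribute only a faint
cytoskeletal haze in the FITC channel, so spindles "stand out" by intensity
and compactness.

**PLA puncta.** Control-condition mitotic cells carry Poisson(12) puncta,
placed 60% inside the spindle ellipse, 25% on the chromosome periphery
(a scaled rim of the plate ellipse), 15% in the surrounding cytoplasm;
interphase cells carry Poisson(3) nuclear puncta. Integrated intensities
are lognormal (meanlog `log(1e5)`, sdlog 0.35) — bright relative to the
background, as rolling-circle amplification products are. The importazole
(IPZ) condition keeps each punctum with probability `1/fold` (default fold
4), so the *expected* per-cell puncta count and sum intensity drop by
exactly the configured fold while placement is untouched.

**Rendering.** Area objects are drawn flat-topped at their in-focus plane
and blurred with a Gaussian defocus kernel whose sigma grows linearly with
distance from focus (1.0 px in focus, +1.2 px per plane). A punctum is a
diffraction-limited 2-D Gaussian (sigma 1.3 px in focus, +0.8 px per plane
of defocus) whose flux is split across z with Gaussian axial weights
normalised over the acquired range; pixel values are exact integrals of
the Gaussian over pixel squares, so total rendered flux equals the
punctum's integrated intensity. The camera model adds per-channel
background (600/500/200 a.u.), Poisson shot noise and Gaussian read noise
(sd 10 a.u.), then quantises to 16-bit. Quantisation belongs to the camera:
with all noise sources disabled the renderer returns the continuous ideal
image, which is what makes the flux-conservation invariant testable to
better than 1% (rounding the wide defocused tails would otherwise lose a
couple of percent).

**What the simulator does not model**: optics-accurate point-spread
functions, chromatic aberration, illumination flatness, autofluorescence
texture, touching or overlapping cells, apoptotic and anaphase figures.
Passing benchmarks on these scenes therefore demonstrates that the
pipeline's logic is correct and self-consistent, not that its default
thresholds transfer to any particular microscope; on real data the
segmentation parameters are meant to be re-tuned per assay.

## Imaging analysis

Processing follows acquisition practice: per field, the z stack is
collapsed by maximum intensity projection, background is subtracted, and
segmentation runs on the projection.

**Background subtraction** offers three estimators: a constant, a channel
percentile (default: the median, robust while objects cover a minority of
the field), and a rolling-ball-style local background via grayscale
morphological opening. Output is clamped at zero.

**Segmentation** thresholds one channel per category (Otsu by default),
labels 8-connected components, and filters by area and circularity.
Circularity is `4*pi*A/P^2` clamped at 1, with the perimeter `P` estimated
by the Vossepoel–Smeulders corner-corrected contour chain length
(`0.980 a + 1.406 b - 0.091 c` over axial steps, diagonal steps and
direction changes). The raw diagonal-corrected chain length was rejected
during development: it overestimates a digitised circle's circumference by
~5% with a strong raster-alignment dependence, which compresses and blurs
the circularity contrast the classifier needs. Under the corrected
estimator, digitised disks of radius >= 10 px measure >= 0.9 (typically
clamping to 1) and 5:1 bars measure < 0.6.

**Classification.** A DAPI object is called mitotic when its
background-subtracted peak intensity exceeds 13,000 a.u. *and* its
circularity is below 0.98, or when it overlaps a pH3-positive mask. The
two cutoffs were calibrated once against the generator: the intensity
floor sits in the empty gap between the interphase and mitotic peak
distributions, and the circularity ceiling is deliberately permissive
because defocus smoothing raises the measured circularity of lobed masses
to ~0.99 while truly round nuclei clamp to 1 — the ceiling excludes
near-ideal disks and the intensity floor carries most of the
discrimination. Each mitotic object is linked to at most one spindle by
greedy one-to-one assignment on centroid distance, restricted to 1.5x the
mean spindle major axis, with ties broken towards the lowest spindle
label.

**Quantification.** The per-cell readout is the PLA-channel sum intensity
within the cell's masks — by default the union of the chromosome mask and
the linked spindle mask for mitotic cells (PLA products concentrate on the
spindle and around chromosomes), and the nuclear mask for interphase
cells. Measurement defaults to the background-subtracted projection (raw
is available); it is additive over disjoint masks and monotone under mask
inclusion.

**Evaluation** against ground truth uses centroid-in-mask matching: a
detection is eligible for a truth cell if its centroid falls inside the
truth object's analytic shape, eligible pairs are matched one-to-one
greedily by distance, coverage is `100 * matched / truth` and precision
`100 * matched / detections`. Precision is our reading of the acquisition
benchmark's "confidence" — the complement of the false-positive fraction
among detections, which is what a manual check of segmented objects
measures; a per-object classifier confidence would be the alternative
reading.

**Condition comparison** uses a two-sided Mann-Whitney U test. When full
enumeration of the permutation distribution is feasible (at most 2e5 group
assignments — this covers every case with `n1+n2 <= 8`) the exact
permutation p-value is computed, which handles ties without approximation;
otherwise the tie-corrected normal approximation with continuity
correction is used. One consequence: a tiny group paired with a very large
one (say 8 vs 190) uses the approximation even though `min(n) <= 8`,
because enumerating C(198,8) assignments is not tractable; at such sizes
the approximation error is far below any decision threshold. Significance
stars follow the usual convention (`****` at p <= 1e-4).

## Interactome post-processing

The parser reads MaxQuant-dialect proteinGroups tables (`+` flags, `;`
gene separators, `Intensity <sample>` columns, 0 = missing). Confidence
filtering applies, sequentially and in fixed order: potential laboratory
contaminants; reverse-decoy identifications; zero unique peptides; at most
one peptide; only-identified-by-site groups; fewer than three MS/MS
spectra; multi-gene associations (any `;`-separated gene-name field). A
row removed by an earlier rule is not recounted, the report reconciles
exactly (`input = removals + survivors`), and marginal per-rule counts are
reported alongside because the sequential tallies are order-sensitive.

Enrichment testing log2-transforms intensities, imputes missing values per
sample column from a down-shifted normal (mean shifted 1.8 sd below the
column's observed mean, width 0.3 sd, seeded — the standard label-free
workflow for left-censored missingness), and applies a two-sided Welch
t-test per group; a hit requires `p < 0.05` *and* positive log2 fold
change. The hit rule uses raw p-values, matching the original analysis
convention; Benjamini-Hochberg q-values are reported for users who want
them. With complete data the statistic reduces to the classical two-sample
t statistic, which the tests check in closed form. A complete-case mode
(`impute = FALSE`) skips groups with fewer than two observed values per
side, with a warning.

Phenotype cross-tabulation joins hit genes against a user-supplied
gene-to-category table (Mitocheck-style categories: mitotic phenotype,
nuclear phenotype, cytokinesis, general features, annotated without
phenotype), counts over the annotated subset, and reports unrounded
percentages plus a display-rounded form. An empty hit list yields an empty
summary rather than a division error; conflicting annotations for one
gene are an error naming the gene.

## Pipeline, determinism, problem sizes

`run_pipeline()` ties the stages together through declared file
interfaces only (TIFF stacks + JSON ground truth + TSV tables in the
output directory), writes a manifest with md5 checksums of every output,
and emits machine- (JSON) and human-readable reports plus a long-format
per-cell intensity table ready for box plots. Identical configuration and
seed reproduce identical checksums; every stochastic component (scene
generation, rendering noise, fixture generation, imputation) draws from an
explicit seed.

Benchmark problem sizes were chosen to exercise the statistics at
realistic cell counts while keeping a laptop-scale footprint: the
segmentation benchmark uses three scenes of 10 fields per culture type
(about 180 cells each), and the treated-vs-control comparison renders
enriched cultures until at least 190 control and 150 treated mitotic
cells are available, the cell counts of the assay this benchmark mirrors.

## Known limitations

- Default thresholds are calibrated to the simulator's intensity scales;
  real acquisitions need per-assay tuning (all parameters are exposed).
- Circularity of small objects (contours under ~16 px) falls back to raw
  chain length and is coarse.
- The enrichment module assumes two conditions with replicate columns; it
  does not model batch structure or paired designs.
- No 3-D (per-plane) segmentation: the pipeline is projection-based by
  design, and structures separable only in z are merged.
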