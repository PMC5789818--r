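# mitopla

Automated analysis of *in situ* proximity ligation assay (is-PLA)
microscopy and AP-MS interactome screens of mitotic cells.

Screens of a bait protein's mitotic partners typically pair two assays: a
co-immunoprecipitation followed by mass spectrometry, which yields a
proteinGroups table to be filtered and tested for bait-vs-IgG enrichment,
and is-PLA microscopy, which renders each candidate interaction as discrete
fluorescent puncta in intact cells and is quantified per cell within
segmentation masks. `mitopla` implements both computational workflows, plus
a ground-truthed simulator of the microscopy so the whole pipeline can be
exercised and benchmarked without any raw data.

For whom: image-analysis and proteomics people who want an auditable,
scriptable replacement for point-and-click acquisition-software macros —
every threshold is a function argument, every stage is unit-tested against
ground truth or a brute-force oracle.

## What it computes

**Imaging.** A multi-field acquisition (fields × z × {DAPI, FITC, TRITC})
is collapsed by maximum intensity projection, background-subtracted, and
segmented by intensity, size and circularity, where circularity is

    C = 4 * pi * A / P^2,   clamped at 1,

with `P` the corner-corrected contour chain length (Vossepoel–Smeulders).
DAPI objects are classified interphase vs mitotic — a mitotic figure is
brighter (condensed chromatin) and non-round, or overlaps a
phospho-histone-H3 mask — and each mitotic figure is linked to its tubulin
spindle. The per-cell readout is the PLA-channel **sum intensity** within
the cell's masks (chromosomes + linked spindle for mitotic cells).
Control vs importazole-treated intensities are compared with a two-sided
Mann-Whitney U test (exact permutation distribution when enumeration is
feasible, tie-corrected normal approximation otherwise).

**Interactome.** MaxQuant-style proteinGroups tables are filtered in fixed
order (contaminants, reverse decoys, unique peptides ≤ 0, peptides ≤ 1,
only-identified-by-site, MS/MS spectra < 3, multi-gene associations), with
an exactly reconciling removal report. Surviving groups are tested for
bait enrichment by Welch t-test on log2 intensities with seeded
down-shifted-normal imputation of missing values (hit: p < 0.05 and
positive fold change), and hits are cross-tabulated against mitotic
phenotype annotations.

## Worked example

```r
library(mitopla)

# a small control acquisition: 4 fields, 50% mitotic (enriched culture)
sp  <- scene_params(field_grid_count = 4L, mitotic_fraction = 0.5, rng_seed = 1L)
gen <- generate_scene(sp)
gen$stack
#> image_stack: 4 fields x 10 z x 3 channels (DAPI/FITC/TRITC), 256x256 px, 0.325 um/px

recs <- analyze_stack(gen$stack, imaging_config())
table(recs$class)
#> interphase    mitotic
#>          4         14

evaluate_segmentation(recs, gen$scene)
#> evaluation: coverage 94.7% (sd 10.0), precision 100.0% (sd 0.0);
#>   matched 18 / truth 19, spurious 0; class agreement 100.0%

# importazole-treated counterpart and the per-cell comparison
ipz  <- generate_scene(update_scene_params(sp, condition = "IPZ", rng_seed = 1001L))
ripz <- analyze_stack(ipz$stack, imaging_config())
compare_conditions(recs$pla_sum_intensity[recs$class == "mitotic"],
                   ripz$pla_sum_intensity[ripz$class == "mitotic"])
#> Mann-Whitney (normal approximation, tie-corrected): U = 139, p = 6.048e-05 ****
#>   CTR n = 14 (median 349919 a.u.), IPZ n = 10 (median 66559 a.u.)
```

Coverage is matched detections over ground-truth cells; precision is the
complement of the false-positive fraction among detections. The treated
condition's per-cell PLA signal collapses (median 66,559 vs 349,919 a.u.),
and the rank test flags the difference at `****` (p ≤ 1e-4) already at
these small cell counts.

The full three-stage pipeline (simulation → imaging → interactome) runs
from a YAML config:

```r
cfg <- default_pipeline_config(seed = 1L, out_dir = "run1")
run_pipeline(cfg)   # writes stacks, masks, per-cell tables, report.json/.txt
```

or from the shell via `Rscript inst/cli/mitopla.R run --config config.yaml`.

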