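#' Segmentation benchmark on synthetic scenes
#'
#' Generates ground-truthed acquisitions (one per seed), runs the default
#' imaging pipeline (projection, background subtraction, segmentation,
#' classification) and scores detections against the ground truth with
#' [evaluate_segmentation()]. Used to benchmark object coverage and
#' precision under asynchronous (`mitotic_fraction` ~ 0.06) and
#' mitosis-enriched (`mitotic_fraction` >= 0.5) culture conditions.
#'
#' @param mitotic_fraction Mitotic fraction of the simulated culture.
#' @param fields Fields per scene.
#' @param seeds Integer vector of scene seeds (one scene per seed).
#' @param config An [imaging_config()].
#' @param ... Further overrides passed to [scene_params()].
#' @return List with `coverage_pct` and `precision_pct` (means over seeds),
#'   `per_seed` (data frame of per-scene results) and `n_cells` (total truth
#'   cells).
#' @export
benchmark_segmentation <- function(mitotic_fraction, fields = 10L,
                                   seeds = 1:3, config = imaging_config(),
                                   ...) {
  per_seed <- lapply(seeds, function(s) {
    sp <- scene_params(field_grid_count = as.integer(fields),
                       mitotic_fraction = mitotic_fraction,
                       rng_seed = as.integer(s), ...)
    gen <- generate_scene(sp)
    recs <- analyze_stack(gen$stack, config)
    ev <- evaluate_segmentation(recs, gen$scene)
    data.frame(seed = s, coverage_pct = ev$coverage_pct,
               precision_pct = ev$precision_pct,
               truth = ev$truth_count, detections = ev$detection_count,
               matched = ev$matched,
               class_agreement_pct = ev$class_agreement_pct)
  })
  per_seed <- do.call(rbind, per_seed)
  list(coverage_pct = mean(per_seed$coverage_pct),
       precision_pct = mean(per_seed$precision_pct),
       per_seed = per_seed, n_cells = sum(per_seed$truth))
}

#' Importazole-comparison benchmark at fixed cell counts
#'
#' Generates a mitosis-enriched control acquisition and an
#' importazole-treated one (generator defaults for the fold reduction),
#' analyses both with the default imaging pipeline, takes the first
#' `n_ctr` / `n_ipz` mitotic per-cell PLA sum intensities in acquisition
#' order, and compares the two samples with the two-sided Mann-Whitney
#' test. Also reports the detected CTR/IPZ median sum-intensity ratio
#' against the configured fold reduction.
#'
#' @param seed Base seed; the treated scene uses `seed + 1000`.
#' @param n_ctr,n_ipz Cells per condition entering the comparison.
#' @param fields_ctr,fields_ipz Fields rendered per condition (enough to
#'   yield the requested cell counts at the default density).
#' @param config An [imaging_config()].
#' @return List with the `pla_comparison`, the per-condition intensity
#'   vectors, `median_ratio` and `configured_fold`.
#' @export
benchmark_ipz_comparison <- function(seed = 1L, n_ctr = 190L, n_ipz = 150L,
                                     fields_ctr = 36L, fields_ipz = 30L,
                                     config = imaging_config()) {
  mk <- function(cond, fields, s) {
    scene_params(field_grid_count = as.integer(fields),
                 image_size_px = c(288L, 288L),
                 cells_per_field = c(6L, 8L), mitotic_fraction = 0.85,
                 condition = cond, rng_seed = as.integer(s))
  }
  sp_ctr <- mk("CTR", fields_ctr, seed)
  sp_ipz <- mk("IPZ", fields_ipz, seed + 1000L)
  ctr <- generate_scene(sp_ctr)
  ipz <- generate_scene(sp_ipz)
  rc <- analyze_stack(ctr$stack, config)
  ri <- analyze_stack(ipz$stack, config)
  mit_c <- rc$pla_sum_intensity[rc$class == "mitotic"]
  mit_i <- ri$pla_sum_intensity[ri$class == "mitotic"]
  x <- mit_c[seq_len(min(n_ctr, length(mit_c)))]
  y <- mit_i[seq_len(min(n_ipz, length(mit_i)))]
  cmp <- compare_conditions(x, y)
  list(comparison = cmp, ctr = x, ipz = y,
       median_ratio = stats::median(x) / stats::median(y),
       configured_fold = sp_ctr$ipz_puncta_fold_reduction)
}
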