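#' Default pipeline configuration
#'
#' Nested configuration for the three-stage workflow: `simulate` (synthetic
#' CTR and IPZ acquisitions plus proteomics fixtures), `imaging` (projection,
#' segmentation, classification, PLA quantification, evaluation, condition
#' comparison) and `interactome` (confidence filtering, enrichment,
#' phenotype annotation). The structure is what [validate_pipeline_config()]
#' enforces: unknown keys anywhere are rejected.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "mitopla_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    log_level = "INFO",
    stages = list(simulate = TRUE, imaging = TRUE, interactome = TRUE),
    simulate = list(
      fields = 6L, z_planes = 10L, image_size_px = 256L,
      cells_per_field = c(4L, 8L), mitotic_fraction = 0.5,
      ipz_puncta_fold_reduction = 4,
      protein_groups = list(n_background = 60L, n_true_interactors = 20L,
                            n_contaminants = 3L, n_reverse = 3L,
                            n_only_by_site = 2L, n_low_peptide = 3L,
                            n_low_unique = 2L, n_low_msms = 3L,
                            n_multigene = 2L, replicates = 3L)),
    imaging = list(pla_selection = "union", measure_on = "subtracted"),
    interactome = list(alpha = 0.05, impute = TRUE)),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks a configuration against the schema of
#' [default_pipeline_config()]: every key must exist in the default
#' structure (unknown keys are rejected with the offending path) and scalar
#' types must match.
#'
#' @param config A list (e.g. loaded from YAML).
#' @return The validated config, with class `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  template <- unclass(default_pipeline_config())
  check <- function(cfg, tpl, path = "") {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown)) {
      stop("unknown configuration key(s): ",
           paste0(path, unknown, collapse = ", "))
    }
    for (nm in names(cfg)) {
      if (is.list(tpl[[nm]]) && !is.null(names(tpl[[nm]]))) {
        if (!is.list(cfg[[nm]])) stop("configuration key ", path, nm,
                                      " must be a section")
        check(cfg[[nm]], tpl[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check(config, template)
  ## merge onto defaults so omitted keys take default values
  merge_cfg <- function(tpl, cfg) {
    for (nm in names(cfg)) {
      tpl[[nm]] <- if (is.list(tpl[[nm]]) && !is.null(names(tpl[[nm]]))) {
        merge_cfg(tpl[[nm]], cfg[[nm]])
      } else cfg[[nm]]
    }
    tpl
  }
  out <- merge_cfg(template, config)
  stopifnot(is.numeric(out$seed),
            out$simulate$mitotic_fraction >= 0, out$simulate$mitotic_fraction <= 1,
            out$simulate$ipz_puncta_fold_reduction >= 1)
  class(out) <- "pipeline_config"
  out
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return A validated `pipeline_config` (`read_pipeline_config`); `path`
#'   invisibly (`write_pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_log <- function(config, level, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (levels[level] >= levels[config$log_level %||% "INFO"]) {
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    paste0(..., collapse = "")))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scene_params_from_config <- function(cfg, condition, seed) {
  scene_params(field_grid_count = cfg$fields, z_planes = cfg$z_planes,
               image_size_px = rep(cfg$image_size_px, length.out = 2L),
               cells_per_field = cfg$cells_per_field,
               mitotic_fraction = cfg$mitotic_fraction,
               condition = condition,
               ipz_puncta_fold_reduction = cfg$ipz_puncta_fold_reduction,
               rng_seed = seed)
}

#' Run the full three-stage pipeline
#'
#' Executes the enabled stages in order (simulate, imaging, interactome).
#' Stages communicate only through files in `out_dir` (TIFF stacks, JSON
#' ground truth, tab-separated tables), so each stage can be re-run or
#' replaced independently. A run manifest with the config hash, seeds and
#' md5 checksums of every written file is saved as `manifest.json`;
#' identical config and seed reproduce identical checksums. On a stage
#' failure, outputs of completed stages and a manifest naming the failed
#' stage are left behind before the error is raised.
#'
#' @param config A `pipeline_config` (validated if plain list).
#' @return The run manifest (list), invisibly on success.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  results <- list()
  completed <- character(0)
  failed <- NULL
  add_file <- function(path) files <<- c(files, path)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    pipeline_log(config, "INFO", "stage ", name, " started")
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) { failed <<- c(name, conditionMessage(e)); FALSE })
    if (ok) {
      completed <<- c(completed, name)
      pipeline_log(config, "INFO", "stage ", name, " completed")
    }
    ok
  }

  ok <- run_stage("simulate", function() {
    sc <- config$simulate
    for (cond in c("CTR", "IPZ")) {
      seed <- config$seed + if (cond == "CTR") 0L else 1000L
      sp <- scene_params_from_config(sc, cond, seed)
      gen <- generate_scene(sp)
      write_scene_json(gen$scene, file.path(out_dir, paste0("scene_", cond, ".json")))
      write_stack(gen$stack, file.path(out_dir, paste0("stack_", cond, ".tif")))
      add_file(file.path(out_dir, paste0("scene_", cond, ".json")))
      add_file(file.path(out_dir, paste0("stack_", cond, ".tif")))
      add_file(file.path(out_dir, paste0("stack_", cond, ".tif.json")))
    }
    pgp <- do.call(pg_fixture_params,
                   c(config$simulate$protein_groups, list(rng_seed = config$seed + 2000L)))
    pg <- generate_protein_groups(pgp)
    write_protein_groups(pg$table, file.path(out_dir, "protein_groups.tsv"))
    utils::write.table(pg$truth, file.path(out_dir, "protein_groups_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- generate_annotation_table(pg$table[["Gene names"]],
                                     rng_seed = config$seed + 3000L)
    utils::write.table(ann, file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_file(file.path(out_dir, "protein_groups.tsv"))
    add_file(file.path(out_dir, "protein_groups_truth.tsv"))
    add_file(file.path(out_dir, "annotation.tsv"))
  })

  if (ok %||% TRUE) ok <- run_stage("imaging", function() {
    icfg <- imaging_config(pla_selection = config$imaging$pla_selection,
                           measure_on = config$imaging$measure_on)
    per_cell <- list()
    for (cond in c("CTR", "IPZ")) {
      stack <- read_stack(file.path(out_dir, paste0("stack_", cond, ".tif")))
      scene <- read_scene_json(file.path(out_dir, paste0("scene_", cond, ".json")))
      recs <- analyze_stack(stack, icfg)
      recs$condition <- rep(cond, nrow(recs))
      per_cell[[cond]] <- recs
      write_cell_records(recs, file.path(out_dir, paste0("cells_", cond, ".tsv")))
      add_file(file.path(out_dir, paste0("cells_", cond, ".tsv")))
      if (cond == "CTR") {
        results$evaluation <<- evaluate_segmentation(recs, scene)
      }
    }
    mit <- function(df) df$pla_sum_intensity[df$class == "mitotic"]
    results$comparison <<- compare_conditions(mit(per_cell$CTR), mit(per_cell$IPZ))
    results$per_cell_table <<- rbind(per_cell$CTR, per_cell$IPZ)
  })

  if (ok %||% TRUE) ok <- run_stage("interactome", function() {
    rows <- parse_protein_groups(file.path(out_dir, "protein_groups.tsv"))
    filt <- apply_confidence_filters(rows)
    results$filter_report <<- filt$report
    ic <- attr(rows, "intensity_columns")
    bait <- grep("bait", ic, value = TRUE)
    igg <- grep("igg", ic, value = TRUE)
    enr <- test_enrichment(filt$survivors, bait, igg,
                           alpha = config$interactome$alpha,
                           impute = config$interactome$impute,
                           seed = config$seed + 4000L)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_file(file.path(out_dir, "enrichment.tsv"))
    results$enrichment <<- enr
    ann <- utils::read.delim(file.path(out_dir, "annotation.tsv"),
                             stringsAsFactors = FALSE)
    results$category_summary <<- annotate_phenotypes(enr$gene_names[enr$hit], ann)
  })

  manifest <- list(
    config_hash = unname(tools::md5sum(local({
      f <- tempfile(); writeLines(as.character(cfg_json), f); f
    }))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mitopla")),
    stages_completed = completed,
    failed_stage = if (is.null(failed)) NULL else failed[1],
    files = as.list(tools::md5sum(files[file.exists(files)])),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (length(results)) write_report(manifest, results, out_dir)
  if (!is.null(failed)) {
    stop("pipeline stage '", failed[1], "' failed: ", failed[2])
  }
  invisible(manifest)
}

#' Write machine- and human-readable pipeline reports
#'
#' Serialises the pipeline results to `report.json` (sections: evaluation,
#' comparison with significance annotation, filter_report, enrichment
#' summary, category_summary) and a plain-text `report.txt`. The per-cell
#' intensity table (`per_cell.tsv`) is written in long format
#' (condition, class, pla_sum_intensity), ready for box plots of PLA signal
#' distributions. Empty results produce a valid empty-section report.
#'
#' @param manifest Run manifest from [run_pipeline()].
#' @param results Named list of result objects (any subset of the sections).
#' @param out_dir Output directory.
#' @return Path of `report.json`, invisibly.
#' @export
write_report <- function(manifest, results, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- list(sections = names(results))
  if (!is.null(results$evaluation)) {
    ev <- results$evaluation
    rep$evaluation <- ev[c("coverage_pct", "coverage_sd", "precision_pct",
                           "precision_sd", "matched", "missed", "spurious",
                           "truth_count", "detection_count",
                           "class_agreement_pct")]
  }
  if (!is.null(results$comparison)) {
    cm <- results$comparison
    rep$comparison <- c(cm[c("U", "p_value", "n_ctr", "n_ipz",
                             "median_ctr", "median_ipz", "method")],
                        list(significance = significance_stars(cm$p_value)))
  }
  if (!is.null(results$filter_report)) {
    fr <- results$filter_report
    rep$filter_report <- list(input_count = fr$input_count,
                              removed = as.list(fr$removed),
                              marginal = as.list(fr$marginal),
                              survivor_count = fr$survivor_count)
  }
  if (!is.null(results$enrichment)) {
    en <- results$enrichment
    rep$enrichment <- list(n_tested = nrow(en), n_hits = sum(en$hit),
                           alpha = attr(en, "alpha"))
  }
  if (!is.null(results$category_summary)) {
    cs <- results$category_summary
    rep$category_summary <- list(n_hits = cs$n_hits,
                                 annotated_count = cs$annotated_count,
                                 unannotated_count = cs$unannotated_count,
                                 categories = cs$categories)
  }
  if (!is.null(results$per_cell_table)) {
    utils::write.table(results$per_cell_table[
      c("condition", "field", "cell_id", "class", "pla_sum_intensity")],
      file.path(out_dir, "per_cell.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rep$per_cell_table <- "per_cell.tsv"
  }
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")

  txt <- c("mitopla pipeline report", strrep("=", 23), "")
  if (!is.null(rep$evaluation)) {
    txt <- c(txt, sprintf("Segmentation: coverage %.1f%% (sd %.1f), precision %.1f%% (sd %.1f)",
                          rep$evaluation$coverage_pct, rep$evaluation$coverage_sd,
                          rep$evaluation$precision_pct, rep$evaluation$precision_sd))
  }
  if (!is.null(rep$comparison)) {
    txt <- c(txt, sprintf("CTR vs IPZ: U = %g, p = %.3g %s (n = %d vs %d)",
                          rep$comparison$U, rep$comparison$p_value,
                          rep$comparison$significance,
                          rep$comparison$n_ctr, rep$comparison$n_ipz))
  }
  if (!is.null(rep$filter_report)) {
    txt <- c(txt, sprintf("Protein groups: %d -> %d after confidence filtering",
                          rep$filter_report$input_count,
                          rep$filter_report$survivor_count))
  }
  if (!is.null(rep$enrichment)) {
    txt <- c(txt, sprintf("Enrichment: %d hits of %d tested (p < %g)",
                          rep$enrichment$n_hits, rep$enrichment$n_tested,
                          rep$enrichment$alpha))
  }
  if (!is.null(rep$category_summary)) {
    txt <- c(txt, sprintf("Phenotypes: %d of %d hits annotated",
                          rep$category_summary$annotated_count,
                          rep$category_summary$n_hits))
  }
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(path)
}

#' Reload a pipeline report
#'
#' @param path Path to `report.json`.
#' @return The report list as written by [write_report()].
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
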