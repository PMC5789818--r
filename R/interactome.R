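#' Parse a MaxQuant-style proteinGroups table
#'
#' Reads a tab-separated proteinGroups table (or accepts an already-loaded
#' data frame) and normalises it: `+`/empty flag columns become logicals, a
#' `;`-separated gene-name field marks a multi-gene association, and
#' intensity columns are identified by the configured sample-name prefix.
#'
#' @param x Path to a tab-separated file, or a data frame with
#'   MaxQuant-dialect columns.
#' @param intensity_prefix Prefix of intensity columns (default
#'   `"Intensity "`).
#' @return A data frame of parsed rows: `group_id`, `gene_names`,
#'   `n_genes`, `unique_peptides`, `peptides`, `msms_count`, logical
#'   `only_by_site` / `reverse` / `contaminant`, plus the original intensity
#'   columns (0 encodes a missing value).
#' @export
parse_protein_groups <- function(x, intensity_prefix = "Intensity ") {
  tab <- if (is.character(x)) {
    utils::read.delim(x, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "")
  } else as.data.frame(x, check.names = FALSE)
  required <- c("Protein IDs", "Gene names", "Unique peptides", "Peptides",
                "MS/MS count", "Only identified by site", "Reverse",
                "Potential contaminant")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  flag <- function(col) !is.na(tab[[col]]) & trimws(as.character(tab[[col]])) == "+"
  count <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !(is.na(tab[[col]]) | tab[[col]] == ""))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           ": '", tab[[col]][bad[1]], "'")
    }
    v[is.na(v)] <- 0
    as.integer(v)
  }
  int_cols <- grep(paste0("^", intensity_prefix), names(tab), value = TRUE)
  out <- data.frame(group_id = as.character(tab[["Protein IDs"]]),
                    gene_names = as.character(tab[["Gene names"]]),
                    n_genes = lengths(strsplit(as.character(tab[["Gene names"]]), ";",
                                               fixed = TRUE)),
                    unique_peptides = count("Unique peptides"),
                    peptides = count("Peptides"),
                    msms_count = count("MS/MS count"),
                    only_by_site = flag("Only identified by site"),
                    reverse = flag("Reverse"),
                    contaminant = flag("Potential contaminant"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in int_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    v[is.na(v)] <- 0
    out[[cc]] <- v
  }
  attr(out, "intensity_columns") <- int_cols
  out
}

#' Sequential confidence filtering of protein groups
#'
#' Applies the identification-confidence ledger in fixed order: potential
#' laboratory contaminants, reverse-decoy identifications, zero unique
#' peptides, at most one peptide, only-identified-by-site groups, fewer
#' than three MS/MS spectra, and ambiguous multi-gene associations. A row
#' removed by an earlier rule is not counted again by later ones; the
#' report reconciles exactly (`input = sum of removals + survivors`).
#' Marginal counts (each rule applied alone to the full input) are also
#' reported, since the sequential tallies are order-sensitive.
#'
#' @param rows Parsed rows from [parse_protein_groups()].
#' @return List with `survivors` (the surviving rows) and `report` (a
#'   `filter_report`: `input_count`, named `removed` and `marginal` vectors,
#'   `survivor_count`, `survivor_ids`).
#' @export
apply_confidence_filters <- function(rows) {
  rules <- list(
    contaminant = function(r) r$contaminant,
    reverse = function(r) r$reverse,
    unique_peptides_le0 = function(r) r$unique_peptides <= 0,
    peptides_le1 = function(r) r$peptides <= 1,
    only_by_site = function(r) r$only_by_site,
    msms_lt3 = function(r) r$msms_count < 3,
    multigene = function(r) r$n_genes > 1)
  n0 <- nrow(rows)
  alive <- rep(TRUE, n0)
  removed <- integer(length(rules)); names(removed) <- names(rules)
  marginal <- integer(length(rules)); names(marginal) <- names(rules)
  for (nm in names(rules)) {
    viol <- rules[[nm]](rows)
    marginal[nm] <- sum(viol)
    hit <- alive & viol
    removed[nm] <- sum(hit)
    alive[hit] <- FALSE
  }
  survivors <- rows[alive, , drop = FALSE]
  rownames(survivors) <- NULL
  attr(survivors, "intensity_columns") <- attr(rows, "intensity_columns")
  report <- structure(list(input_count = n0, removed = removed,
                           marginal = marginal,
                           survivor_count = nrow(survivors),
                           survivor_ids = survivors$group_id),
                      class = "filter_report")
  stopifnot(report$input_count - sum(report$removed) == report$survivor_count)
  list(survivors = survivors, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("confidence filtering:", x$input_count, "->", x$survivor_count,
      "protein groups\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  %-22s removed %4d (marginal %4d)\n", nm,
                x$removed[nm], x$marginal[nm]))
  }
  invisible(x)
}

#' Bait-versus-IgG enrichment test
#'
#' Label-free enrichment analysis of surviving protein groups: intensities
#' are log2-transformed (0 = missing), missing values are imputed per
#' sample column from a down-shifted normal distribution (mean shifted by
#' `shift` standard deviations below the column's observed mean, width
#' `width` times the observed standard deviation; seeded, hence
#' reproducible), and each group is tested with a two-sided Welch t-test of
#' bait versus control log2 intensities. A group is a hit when `p < alpha`
#' and its mean bait intensity exceeds the control mean. Benjamini-Hochberg
#' q-values are reported alongside the raw p-values the hit call uses.
#' With `impute = FALSE` only observed values are used, and groups with
#' fewer than two valid values on either side are skipped with a warning.
#'
#' @param survivors Rows from [apply_confidence_filters()] (or
#'   [parse_protein_groups()]).
#' @param bait_samples,control_samples Intensity column names of the two
#'   groups (at least 2 each).
#' @param alpha Significance level for the hit call.
#' @param impute Impute missing values from the down-shifted normal?
#' @param shift,width Imputation parameters in units of the observed
#'   per-column standard deviation.
#' @param seed Integer seed for the imputation draws.
#' @return An `enrichment_result` data frame: `group_id`, `gene_names`,
#'   `log2fc`, `t_stat`, `p_value`, `q_value`, `hit`, `n_imputed`,
#'   `skipped`; imputation metadata in attributes.
#' @export
test_enrichment <- function(survivors, bait_samples, control_samples,
                            alpha = 0.05, impute = TRUE,
                            shift = 1.8, width = 0.3, seed = 1L) {
  cols <- c(bait_samples, control_samples)
  missing_cols <- setdiff(cols, names(survivors))
  if (length(missing_cols)) {
    stop("intensity column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  if (length(bait_samples) < 2L || length(control_samples) < 2L) {
    stop("at least 2 replicates per group are required")
  }
  m <- as.matrix(survivors[, cols, drop = FALSE])
  lm2 <- suppressWarnings(log2(m))
  lm2[!is.finite(lm2)] <- NA  # zeros encode missing
  n_imputed_row <- integer(nrow(m))
  if (impute && anyNA(lm2) && nrow(m)) {
    set.seed(seed)
    for (j in seq_len(ncol(lm2))) {
      obs <- lm2[, j][!is.na(lm2[, j])]
      miss <- which(is.na(lm2[, j]))
      if (!length(miss)) next
      mu <- mean(obs); sdv <- stats::sd(obs)
      if (!is.finite(sdv) || sdv == 0) sdv <- 0.3
      lm2[miss, j] <- stats::rnorm(length(miss), mu - shift * sdv, width * sdv)
      n_imputed_row[miss] <- n_imputed_row[miss] + 1L
    }
  }
  bait_idx <- match(bait_samples, cols); ctrl_idx <- match(control_samples, cols)
  res <- lapply(seq_len(nrow(lm2)), function(i) {
    b <- lm2[i, bait_idx]; ct <- lm2[i, ctrl_idx]
    b <- b[!is.na(b)]; ct <- ct[!is.na(ct)]
    if (length(b) < 2L || length(ct) < 2L) {
      return(data.frame(log2fc = NA_real_, t_stat = NA_real_,
                        p_value = NA_real_, skipped = TRUE))
    }
    if (stats::var(b) == 0 && stats::var(ct) == 0) {
      ## degenerate: no within-group variance; separation decides
      eq <- isTRUE(all.equal(mean(b), mean(ct)))
      return(data.frame(log2fc = mean(b) - mean(ct), t_stat = if (eq) 0 else Inf,
                        p_value = if (eq) 1 else .Machine$double.xmin,
                        skipped = FALSE))
    }
    tt <- stats::t.test(b, ct, var.equal = FALSE)
    data.frame(log2fc = mean(b) - mean(ct), t_stat = unname(tt$statistic),
               p_value = tt$p.value, skipped = FALSE)
  })
  res <- do.call(rbind, res)
  if (any(res$skipped)) {
    warning(sum(res$skipped), " group(s) skipped: fewer than 2 valid values per side")
  }
  out <- data.frame(group_id = survivors$group_id,
                    gene_names = survivors$gene_names,
                    log2fc = res$log2fc, t_stat = res$t_stat,
                    p_value = res$p_value,
                    q_value = stats::p.adjust(res$p_value, method = "BH"),
                    hit = !res$skipped & !is.na(res$p_value) &
                      res$p_value < alpha & res$log2fc > 0,
                    n_imputed = n_imputed_row,
                    skipped = res$skipped,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "imputation") <- list(enabled = impute, shift = shift,
                                  width = width, seed = seed)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cross-tabulate hits against phenotype annotations
#'
#' Looks up each hit gene in a gene-to-category annotation table
#' (Mitocheck-like) and tallies the annotated subset by phenotype category.
#' Percentages are reported unrounded over the annotated count, together
#' with a display-rounded form. Hits absent from the table are counted as
#' unannotated; a gene carrying two conflicting annotations is an error.
#'
#' @param hit_genes Character vector of hit gene names.
#' @param annotation Data frame with columns `gene` and `category`.
#' @return A `category_summary`: `n_hits`, `annotated_count`,
#'   `unannotated_count`, and a `categories` data frame with `count`,
#'   `percentage` (unrounded) and `display` (paper-style rounding).
#' @export
annotate_phenotypes <- function(hit_genes, annotation) {
  stopifnot(all(c("gene", "category") %in% names(annotation)))
  dup <- unique(annotation$gene[duplicated(annotation$gene)])
  conflict <- dup[vapply(dup, function(g) {
    length(unique(annotation$category[annotation$gene == g])) > 1L
  }, logical(1))]
  if (length(conflict)) {
    stop("conflicting annotations for gene(s): ", paste(conflict, collapse = ", "))
  }
  hit_genes <- unique(hit_genes)
  cat_of <- annotation$category[match(hit_genes, annotation$gene)]
  annotated <- !is.na(cat_of)
  n_ann <- sum(annotated)
  cats <- sort(unique(annotation$category))
  counts <- vapply(cats, function(cc) sum(cat_of[annotated] == cc), integer(1))
  pct <- if (n_ann > 0) 100 * counts / n_ann else rep(NA_real_, length(counts))
  categories <- data.frame(category = cats, count = counts,
                           percentage = pct,
                           display = ifelse(is.na(pct), NA_character_,
                                            paste0(round(pct, 2), "%")),
                           stringsAsFactors = FALSE)
  rownames(categories) <- NULL
  structure(list(n_hits = length(hit_genes), annotated_count = n_ann,
                 unannotated_count = length(hit_genes) - n_ann,
                 categories = categories),
            class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat("phenotype annotation:", x$annotated_count, "of", x$n_hits,
      "hits annotated\n")
  if (x$annotated_count > 0) {
    for (i in seq_len(nrow(x$categories))) {
      cat(sprintf("  %-24s %4d (%.2f%%)\n", x$categories$category[i],
                  x$categories$count[i], x$categories$percentage[i]))
    }
  }
  invisible(x)
}
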