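#' Fixture parameters for a synthetic proteinGroups table
#'
#' Describes a MaxQuant-style proteinGroups fixture: clean background
#' proteins (equal bait and IgG intensities), planted true interactors
#' (bait-enriched), and rows violating exactly one confidence-filter rule
#' each (contaminant, reverse-decoy, zero unique peptides, at most one
#' peptide, only-identified-by-site, fewer than three MS/MS spectra, or a
#' multi-gene association).
#'
#' @param n_background,n_true_interactors Counts of clean rows.
#' @param n_contaminants,n_reverse,n_only_by_site,n_low_peptide,n_low_msms,n_multigene
#'   Counts of rows violating the respective rule.
#' @param n_low_unique Rows with zero unique peptides (but >1 peptides).
#' @param bait_log2_enrichment_mean,bait_log2_enrichment_sd Planted log2
#'   bait-over-IgG enrichment of true interactors.
#' @param replicates Replicates per group (>= 2).
#' @param missing_rate_igg Probability that an IgG intensity is missing
#'   (encoded 0) for a true interactor.
#' @param rng_seed Integer seed.
#' @return A list of class `pg_fixture_params`.
#' @export
pg_fixture_params <- function(n_background = 100L, n_true_interactors = 30L,
                              n_contaminants = 0L, n_reverse = 0L,
                              n_only_by_site = 0L, n_low_peptide = 0L,
                              n_low_unique = 0L, n_low_msms = 0L,
                              n_multigene = 0L,
                              bait_log2_enrichment_mean = 4,
                              bait_log2_enrichment_sd = 0.5,
                              replicates = 3L,
                              missing_rate_igg = 0,
                              rng_seed = 1L) {
  p <- list(n_background = as.integer(n_background),
            n_true_interactors = as.integer(n_true_interactors),
            n_contaminants = as.integer(n_contaminants),
            n_reverse = as.integer(n_reverse),
            n_only_by_site = as.integer(n_only_by_site),
            n_low_peptide = as.integer(n_low_peptide),
            n_low_unique = as.integer(n_low_unique),
            n_low_msms = as.integer(n_low_msms),
            n_multigene = as.integer(n_multigene),
            bait_log2_enrichment_mean = bait_log2_enrichment_mean,
            bait_log2_enrichment_sd = bait_log2_enrichment_sd,
            replicates = as.integer(replicates),
            missing_rate_igg = missing_rate_igg,
            rng_seed = as.integer(rng_seed))
  counts <- unlist(p[startsWith(names(p), "n_")])
  stopifnot(all(counts >= 0L), p$replicates >= 2L,
            p$missing_rate_igg >= 0, p$missing_rate_igg <= 1)
  class(p) <- "pg_fixture_params"
  p
}

#' Generate a synthetic MaxQuant-style proteinGroups table
#'
#' Builds a tab-separated-ready data frame in the MaxQuant proteinGroups
#' dialect (flags encoded as `"+"`, missing intensities as 0) together with
#' truth labels recording each row's role. Exactly the requested number of
#' rows violates each filter rule; planted true interactors carry the
#' configured log2 bait enrichment.
#'
#' @param params A [pg_fixture_params()] object.
#' @return List with `table` (data frame with MaxQuant-dialect columns),
#'   `truth` (data frame `group_id`, `role`), `bait_samples` and
#'   `igg_samples` (intensity column names).
#' @export
generate_protein_groups <- function(params) {
  set.seed(params$rng_seed)
  reps <- params$replicates
  bait_cols <- paste0("Intensity bait_", seq_len(reps))
  igg_cols <- paste0("Intensity igg_", seq_len(reps))

  mk_row <- function(id, gene, role, upep, pep, msms, site, rev, cont,
                     bait_log2, igg_log2) {
    bait <- round(2^bait_log2)
    igg <- round(2^igg_log2)
    igg[igg_log2 < 0] <- 0
    row <- data.frame(`Protein IDs` = id, `Gene names` = gene,
                      `Unique peptides` = upep, Peptides = pep,
                      `MS/MS count` = msms,
                      `Only identified by site` = site, Reverse = rev,
                      `Potential contaminant` = cont,
                      check.names = FALSE, stringsAsFactors = FALSE)
    row[bait_cols] <- as.list(bait)
    row[igg_cols] <- as.list(igg)
    attr(row, "role") <- role
    row
  }
  rows <- list(); roles <- character(); k <- 0L
  add <- function(row) {
    k <<- k + 1L
    rows[[k]] <<- row
    roles[k] <<- attr(row, "role")
  }
  clean_counts <- function() {
    pep <- sample(3:25, 1L)
    list(upep = max(1L, pep - sample(0:2, 1L)), pep = pep,
         msms = pep + sample(2:40, 1L))
  }
  base_log2 <- function() stats::rnorm(1, 26, 1.5)

  for (i in seq_len(params$n_background)) {
    cc <- clean_counts(); b <- base_log2()
    add(mk_row(sprintf("BG%04d", i), sprintf("BGGENE%d", i), "background",
               cc$upep, cc$pep, cc$msms, "", "", "",
               b + stats::rnorm(reps, 0, 0.4), b + stats::rnorm(reps, 0, 0.4)))
  }
  for (i in seq_len(params$n_true_interactors)) {
    cc <- clean_counts(); b <- base_log2()
    d <- stats::rnorm(1, params$bait_log2_enrichment_mean,
                      params$bait_log2_enrichment_sd)
    igg <- b + stats::rnorm(reps, 0, 0.4)
    igg[stats::runif(reps) < params$missing_rate_igg] <- -1  # encode missing
    add(mk_row(sprintf("TI%04d", i), sprintf("TIGENE%d", i), "true_interactor",
               cc$upep, cc$pep, cc$msms, "", "", "",
               b + d + stats::rnorm(reps, 0, 0.4), igg))
  }
  viol <- function(n, role, f) {
    for (i in seq_len(n)) {
      cc <- clean_counts(); b <- base_log2()
      args <- list(id = sprintf("%s%04d", toupper(substr(role, 1, 3)), i),
                   gene = sprintf("%sGENE%d", toupper(substr(role, 1, 3)), i),
                   role = role, upep = cc$upep, pep = cc$pep, msms = cc$msms,
                   site = "", rev = "", cont = "",
                   bait_log2 = b + stats::rnorm(reps, 0, 0.4),
                   igg_log2 = b + stats::rnorm(reps, 0, 0.4))
      add(do.call(mk_row, f(args)))
    }
  }
  viol(params$n_contaminants, "contaminant", function(a) { a$cont <- "+"; a })
  viol(params$n_reverse, "reverse", function(a) { a$rev <- "+"; a })
  viol(params$n_low_unique, "low_unique", function(a) {
    a$upep <- 0L; a$pep <- max(2L, a$pep); a })
  viol(params$n_low_peptide, "low_peptide", function(a) {
    ## exactly one (unique) peptide so only the peptides<=1 rule fires
    a$pep <- 1L; a$upep <- 1L; a })
  viol(params$n_only_by_site, "only_by_site", function(a) { a$site <- "+"; a })
  viol(params$n_low_msms, "low_msms", function(a) { a$msms <- sample(0:2, 1L); a })
  viol(params$n_multigene, "multigene", function(a) {
    a$gene <- paste0(a$gene, ";ALT", sample(100:999, 1L)); a })

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ## deterministic shuffle so roles are not positionally encoded
  ord <- sample(nrow(tab))
  tab <- tab[ord, , drop = FALSE]
  roles <- roles[ord]
  rownames(tab) <- NULL
  list(table = tab,
       truth = data.frame(group_id = tab[["Protein IDs"]], role = roles,
                          stringsAsFactors = FALSE),
       bait_samples = bait_cols, igg_samples = igg_cols)
}

#' Write a proteinGroups fixture table
#'
#' @param table Data frame from [generate_protein_groups()].
#' @param path Output path (tab-separated, UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a gene-to-phenotype annotation fixture
#'
#' Emulates a Mitocheck-like annotation table: a subset of the supplied
#' genes is annotated, each with one phenotype category drawn with the
#' given probabilities.
#'
#' @param genes Character vector of gene names.
#' @param annotated_fraction Fraction of genes present in the table.
#' @param category_probs Named probabilities over the phenotype categories.
#' @param rng_seed Integer seed.
#' @return Data frame with columns `gene`, `category`.
#' @export
generate_annotation_table <- function(genes, annotated_fraction = 0.72,
                                      category_probs = c(mitotic_phenotype = 0.44,
                                                         nuclear_phenotype = 0.04,
                                                         cytokinesis = 0.05,
                                                         general_features = 0.26,
                                                         annotated_no_phenotype = 0.21),
                                      rng_seed = 1L) {
  set.seed(rng_seed)
  genes <- unique(genes)
  ann <- genes[stats::runif(length(genes)) < annotated_fraction]
  data.frame(gene = ann,
             category = sample(names(category_probs), length(ann),
                               replace = TRUE, prob = category_probs),
             stringsAsFactors = FALSE)
}
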