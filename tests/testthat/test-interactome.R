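pg_header <- c("Protein IDs", "Gene names", "Unique peptides", "Peptides",
               "MS/MS count", "Only identified by site", "Reverse",
               "Potential contaminant", "Intensity bait_1", "Intensity bait_2",
               "Intensity igg_1", "Intensity igg_2")

empty_pg <- function() {
  x <- as.data.frame(matrix(character(0), 0, length(pg_header)),
                     stringsAsFactors = FALSE)
  names(x) <- pg_header
  x
}

one_row <- function(...) {
  v <- list(...)
  x <- data.frame(`Protein IDs` = "P1", `Gene names` = "G1",
                  `Unique peptides` = 2L, Peptides = 5L, `MS/MS count` = 9L,
                  `Only identified by site` = "", Reverse = "",
                  `Potential contaminant` = "",
                  `Intensity bait_1` = 1e7, `Intensity bait_2` = 1e7,
                  `Intensity igg_1` = 1e6, `Intensity igg_2` = 1e6,
                  check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(v)) x[[nm]] <- v[[nm]]
  x
}

test_that("parser handles empty tables, flags and dialect details", {
  expect_equal(nrow(parse_protein_groups(empty_pg())), 0L)
  r <- parse_protein_groups(one_row(Reverse = "+"))
  expect_true(r$reverse)
  expect_false(r$contaminant)
  r2 <- parse_protein_groups(one_row(`Gene names` = "KPNB1;RAN"))
  expect_equal(r2$n_genes, 2L)
  expect_equal(attr(r, "intensity_columns"),
               c("Intensity bait_1", "Intensity bait_2",
                 "Intensity igg_1", "Intensity igg_2"))
})

test_that("parser errors name the missing column and the bad row", {
  bad <- one_row(); bad[["Peptides"]] <- NULL
  expect_error(parse_protein_groups(bad), "Peptides")
  bad2 <- one_row(Peptides = "five")
  expect_error(parse_protein_groups(bad2), "row 1")
})

test_that("generated fixtures round-trip through write and parse", {
  pg <- generate_protein_groups(pg_fixture_params(n_background = 8L,
                                                  n_true_interactors = 4L,
                                                  n_reverse = 3L,
                                                  rng_seed = 3L))
  expect_equal(sum(pg$table$Reverse == "+"), 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_protein_groups(pg$table, f)
  rows <- parse_protein_groups(f)
  expect_equal(nrow(rows), nrow(pg$table))
  expect_equal(rows$group_id, pg$table[["Protein IDs"]])
  expect_equal(rows$peptides, pg$table$Peptides)
  expect_equal(rows$reverse, pg$table$Reverse == "+")
  expect_equal(rows[["Intensity bait_1"]], pg$table[["Intensity bait_1"]])
})

test_that("each confidence rule fires on its planted violation, in order", {
  ## single-rule checks
  r <- parse_protein_groups(one_row(`MS/MS count` = 2L))
  expect_equal(unname(apply_confidence_filters(r)$report$removed["msms_lt3"]), 1L)
  clean <- parse_protein_groups(one_row(`Unique peptides` = 1L, Peptides = 2L,
                                        `MS/MS count` = 3L))
  out <- apply_confidence_filters(clean)
  expect_equal(out$report$survivor_count, 1L)
  expect_true(all(out$report$removed == 0L))

  ## planted fixture: sequential tallies equal the planted counts
  planted <- c(n_contaminants = 2L, n_reverse = 3L, n_low_unique = 2L,
               n_low_peptide = 4L, n_only_by_site = 2L, n_low_msms = 3L,
               n_multigene = 2L)
  pg <- generate_protein_groups(do.call(pg_fixture_params,
    c(list(n_background = 50L, n_true_interactors = 10L, rng_seed = 7L),
      as.list(planted))))
  rows <- parse_protein_groups(pg$table)
  rep <- apply_confidence_filters(rows)$report
  expect_equal(unname(rep$removed[c("contaminant", "reverse",
                                    "unique_peptides_le0", "peptides_le1",
                                    "only_by_site", "msms_lt3", "multigene")]),
               unname(planted[c("n_contaminants", "n_reverse", "n_low_unique",
                                "n_low_peptide", "n_only_by_site", "n_low_msms",
                                "n_multigene")]))
  expect_equal(rep$survivor_count, 60L)
})

test_that("filter conservation holds on arbitrary inputs", {
  set.seed(13)
  for (rep in 1:5) {
    pg <- generate_protein_groups(pg_fixture_params(
      n_background = sample(5:40, 1), n_true_interactors = sample(0:10, 1),
      n_contaminants = sample(0:5, 1), n_reverse = sample(0:5, 1),
      n_low_peptide = sample(0:5, 1), n_low_msms = sample(0:5, 1),
      n_multigene = sample(0:5, 1), rng_seed = rep))
    rows <- parse_protein_groups(pg$table)
    out <- apply_confidence_filters(rows)
    expect_equal(out$report$input_count,
                 sum(out$report$removed) + out$report$survivor_count)
    expect_equal(length(out$report$survivor_ids), out$report$survivor_count)
  }
})

test_that("identical bait and control intensities are never hits", {
  r <- parse_protein_groups(one_row(`Intensity igg_1` = 1e7,
                                    `Intensity igg_2` = 1e7))
  ## add within-group jitter so the t-test is defined
  r[["Intensity bait_2"]] <- 1.0001e7; r[["Intensity igg_2"]] <- 1.0001e7
  enr <- test_enrichment(r, c("Intensity bait_1", "Intensity bait_2"),
                         c("Intensity igg_1", "Intensity igg_2"))
  expect_equal(enr$log2fc, 0)
  expect_false(enr$hit)
})

test_that("a forced 16-fold separation is a hit with log2fc = 4", {
  tab <- one_row(`Intensity bait_1` = 2^30, `Intensity bait_2` = 2^30 * 1.001,
                 `Intensity igg_1` = 2^26, `Intensity igg_2` = 2^26 * 1.001)
  r <- parse_protein_groups(tab)
  enr <- test_enrichment(r, c("Intensity bait_1", "Intensity bait_2"),
                         c("Intensity igg_1", "Intensity igg_2"))
  expect_equal(enr$log2fc, 4, tolerance = 1e-6)
  expect_true(enr$hit)
})

test_that("with complete data and equal variances the test reduces to the t statistic", {
  set.seed(21)
  b <- 2^rnorm(3, 28, 0.3); ct <- 2^rnorm(3, 26, 0.3)
  tab <- one_row()
  for (i in 1:3) {
    tab[[paste0("Intensity bait_", i)]] <- b[i]
    tab[[paste0("Intensity igg_", i)]] <- ct[i]
  }
  r <- parse_protein_groups(tab)
  enr <- test_enrichment(r, paste0("Intensity bait_", 1:3),
                         paste0("Intensity igg_", 1:3))
  ## closed-form Welch statistic on the log2 values
  lb <- log2(b); lc <- log2(ct)
  t_ref <- (mean(lb) - mean(lc)) / sqrt(var(lb) / 3 + var(lc) / 3)
  expect_equal(enr$t_stat, t_ref, tolerance = 1e-10)
  expect_equal(enr$p_value, stats::t.test(lb, lc)$p.value, tolerance = 1e-10)
})

test_that("planted interactors are recovered (>= 90% sensitivity, <= 10% background hits)", {
  pg <- generate_protein_groups(pg_fixture_params(
    n_background = 200L, n_true_interactors = 40L,
    bait_log2_enrichment_mean = 4, bait_log2_enrichment_sd = 0.5,
    replicates = 3L, rng_seed = 7L))
  rows <- parse_protein_groups(pg$table)
  enr <- test_enrichment(rows, pg$bait_samples, pg$igg_samples, seed = 7L)
  m <- merge(enr, pg$truth, by = "group_id")
  sens <- mean(m$hit[m$role == "true_interactor"])
  fpr <- mean(m$hit[m$role == "background"])
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.1)
})

test_that("imputation is seed-deterministic and only affects groups with missing values", {
  pg <- generate_protein_groups(pg_fixture_params(
    n_background = 30L, n_true_interactors = 10L, missing_rate_igg = 0.5,
    rng_seed = 5L))
  rows <- parse_protein_groups(pg$table)
  a <- test_enrichment(rows, pg$bait_samples, pg$igg_samples, seed = 42L)
  b <- test_enrichment(rows, pg$bait_samples, pg$igg_samples, seed = 42L)
  expect_identical(a$p_value, b$p_value)
  c2 <- test_enrichment(rows, pg$bait_samples, pg$igg_samples, seed = 43L)
  expect_false(identical(a$p_value, c2$p_value))
  ## complete-case mode changes results only where values were missing
  suppressWarnings(cc <- test_enrichment(rows, pg$bait_samples, pg$igg_samples,
                                         impute = FALSE))
  no_missing <- a$n_imputed == 0
  expect_equal(a$p_value[no_missing], cc$p_value[no_missing])
})

test_that("phenotype cross-tabulation reproduces printed-tally arithmetic", {
  ## counts as in the published cross-annotation: 195 annotated hits of
  ## which 86 mitotic, 7 nuclear, 10 cytokinesis, 51 general
  counts <- c(mitotic_phenotype = 86, nuclear_phenotype = 7,
              cytokinesis = 10, general_features = 51,
              annotated_no_phenotype = 195 - 86 - 7 - 10 - 51)
  genes <- paste0("GENE", seq_len(272))
  ann <- data.frame(gene = genes[seq_len(195)],
                    category = rep(names(counts), counts))
  cs <- annotate_phenotypes(genes, ann)
  expect_equal(cs$annotated_count, 195L)
  expect_equal(cs$unannotated_count, 77L)
  got <- setNames(cs$categories$percentage, cs$categories$category)
  expect_equal(unname(got["mitotic_phenotype"]), 100 * 86 / 195, tolerance = 1e-12)
  expect_equal(round(got[["mitotic_phenotype"]], 2), 44.10)
  expect_equal(round(got[["nuclear_phenotype"]], 2), 3.59)
  expect_equal(round(got[["cytokinesis"]], 2), 5.13)
  expect_equal(round(got[["general_features"]], 2), 26.15)
  expect_equal(sum(cs$categories$count), cs$annotated_count)
})

test_that("empty hit lists give an empty summary, not a division error", {
  ann <- data.frame(gene = "A", category = "mitotic_phenotype")
  cs <- annotate_phenotypes(character(0), ann)
  expect_equal(cs$annotated_count, 0L)
  expect_true(all(is.na(cs$categories$percentage)))
})

test_that("category counts always sum to the annotated count", {
  set.seed(99)
  genes <- paste0("G", 1:600)
  ann <- generate_annotation_table(genes, rng_seed = 17L)
  hits <- sample(genes, 500)
  cs <- annotate_phenotypes(hits, ann)
  ## conservation by direct recount
  expect_equal(sum(cs$categories$count), cs$annotated_count)
  expect_equal(cs$annotated_count + cs$unannotated_count, length(unique(hits)))
})

test_that("conflicting annotations are rejected with the gene named", {
  ann <- data.frame(gene = c("A", "A"), category = c("cytokinesis",
                                                     "mitotic_phenotype"))
  expect_error(annotate_phenotypes("A", ann), "A")
})
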