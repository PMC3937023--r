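# Proteome filtering, id collapsing, the five-way partition and concordance.

test_that("proteome filtering enforces confidence and keeps max duplicates", {
  df <- data.frame(protein_id = c("P1", "P2", "P2", "P3"),
                   abundance = c(1.0, 3.0, 7.5, 2.0),
                   confidence = c(95, 99, 100, 100),
                   stringsAsFactors = FALSE)
  out <- filter_proteome(df)
  expect_equal(out$protein_id, c("P2", "P3"))
  expect_equal(out$abundance[out$protein_id == "P2"], 7.5)
  expect_identical(filter_proteome(out), out)  # idempotent
  expect_equal(nrow(filter_proteome(df[0, ])), 0)
  expect_error(filter_proteome(data.frame(protein_id = "P",
                                          abundance = -1,
                                          confidence = 99)),
               "negative")
})

test_that("id collapsing pairs each protein with its most abundant gene", {
  mapping <- data.frame(gene_id = c("gA", "gB", "gC"),
                        protein_id = c("P1", "P1", "P2"),
                        stringsAsFactors = FALSE)
  ab <- c(gA = 5.0, gB = 8.0, gC = 2.0)
  out <- collapse_ids(mapping, ab)
  expect_equal(out$gene_id[out$protein_id == "P1"], "gB")
  expect_equal(out$gene_id[out$protein_id == "P2"], "gC")

  tie <- collapse_ids(mapping, c(gA = 5.0, gB = 5.0, gC = 2.0))
  expect_equal(tie$gene_id[tie$protein_id == "P1"], "gA")

  one <- collapse_ids(data.frame(gene_id = "gX", protein_id = "P9"),
                      c(gX = 1))
  expect_equal(one$gene_id, "gX")
})

test_that("the five groups partition genes and proteins at n = 3", {
  calls <- rbind(gAll = c(TRUE, TRUE, TRUE),    # protein -> both_alln
                 gTwo = c(TRUE, TRUE, FALSE),   # no protein -> mrna_1to9
                 gNoP = c(TRUE, TRUE, TRUE),    # no protein -> mrna_alln
                 gOff = c(FALSE, FALSE, FALSE), # never expressed
                 gPart = c(FALSE, TRUE, FALSE)) # protein -> protein_and_1to9
  colnames(calls) <- paste0("s", 1:3)
  proteome <- data.frame(protein_id = c("P1", "P2", "P3"),
                         abundance = c(1, 2, 3), confidence = c(99, 100, 99),
                         stringsAsFactors = FALSE)
  mapping <- data.frame(gene_id = c("gAll", "gPart", "gOff"),
                        protein_id = c("P1", "P2", "P3"),
                        stringsAsFactors = FALSE)
  gr <- partition_groups(calls, proteome, mapping)
  expect_equal(gr$both_alln, "P1")
  expect_equal(gr$protein_and_mrna_1to9, "P2")
  expect_equal(gr$protein_no_mrna, "P3")  # mapped only to a silent gene
  expect_equal(gr$mrna_alln_no_protein, "gNoP")
  expect_equal(gr$mrna_1to9_no_protein, "gTwo")
  # protein-side groups partition the proteome
  expect_equal(sort(c(gr$both_alln, gr$protein_no_mrna,
                      gr$protein_and_mrna_1to9)),
               sort(proteome$protein_id))
  # the five groups are pairwise disjoint
  ids <- c(gr$both_alln, gr$mrna_alln_no_protein, gr$protein_no_mrna,
           gr$mrna_1to9_no_protein, gr$protein_and_mrna_1to9)
  expect_equal(anyDuplicated(ids), 0)

  expect_warning(partition_groups(calls, proteome,
                                  rbind(mapping,
                                        data.frame(gene_id = "ghost",
                                                   protein_id = "P1"))),
                 "unknown ids")
})

test_that("partition summary reproduces the headline percentages", {
  groups <- list(both_alln = sprintf("a%d", 1:2338),
                 mrna_alln_no_protein = sprintf("b%d", 1:3226),
                 protein_no_mrna = sprintf("c%d", 1:432),
                 mrna_1to9_no_protein = sprintf("d%d", 1:3634),
                 protein_and_mrna_1to9 = sprintf("e%d", 1:774))
  s <- summarize_partition(groups)
  expect_equal(s$proteome_size, 3544)
  expect_equal(s$mrna_alln_size, 5564)
  expect_equal(round(s$pct_proteins_with_mrna, 1), 87.8)
  expect_equal(round(s$pct_proteins_no_mrna, 1), 12.2)
  expect_equal(round(s$pct_proteins_mrna_alln), 66)
})

test_that("Spearman concordance handles ranks, ties and constants", {
  mono <- data.frame(transcript_abundance = 1:10,
                     protein_abundance = (1:10)^3)
  expect_equal(concordance_spearman(mono)$rho, 1)

  tri <- data.frame(transcript_abundance = c(1, 2, 3),
                    protein_abundance = c(3, 1, 2))
  expect_equal(concordance_spearman(tri)$rho, -0.5)

  cst <- data.frame(transcript_abundance = rep(1, 5),
                    protein_abundance = 1:5)
  expect_equal(concordance_spearman(cst)$flag, "constant")
  expect_error(concordance_spearman(mono[1:2, ]), "at least 3")
})

test_that("planted copula correlations are recovered across the rho range", {
  targets <- c(0, 0.3, 0.8)
  set.seed(27)
  for (rho in targets) {
    want <- (6 / pi) * asin(rho / 2)
    for (rep_ in 1:3) {
      z <- rnorm(2000)
      pairs <- data.frame(transcript_abundance = exp(z),
                          protein_abundance = exp(rho * z +
                                                    sqrt(1 - rho^2) *
                                                    rnorm(2000)))
      got <- concordance_spearman(pairs)$rho
      expect_lt(abs(got - want), 3 / sqrt(2000 - 3) + 0.02)
    }
  }
})

test_that("the full proteome arm joins, partitions and correlates", {
  em <- simulate_expression_cohort(n_genes = 4000, n_pseudogenes = 20,
                                   seed = 19)
  cfg <- proteome_sim_config(n_overlap_pairs = 300, n_protein_only = 50,
                             n_mrna_only_all = 400, n_overlap_1to9 = 80,
                             n_mrna_only_1to9 = 350, n_low_confidence = 40,
                             n_duplicates = 30, seed = 20)
  sim <- simulate_proteome(em, cfg)
  cs <- proteome_concordance(sim$expression, sim$proteome, sim$mapping)
  s <- cs$summary
  expect_equal(s$n_both_alln, 300)
  expect_equal(s$n_protein_no_mrna, 50)
  expect_equal(s$n_mrna_alln_no_protein, 400)
  expect_equal(s$n_protein_and_mrna_1to9, 80)
  expect_equal(s$n_mrna_1to9_no_protein, 350)
  expect_equal(s$proteome_size, 430)
  expect_equal(cs$spearman$n, 300)
  # planted copula at the default rho recovers a weak positive concordance
  expect_lt(abs(cs$spearman$rho - 0.311), 0.15)
})
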