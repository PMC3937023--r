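# Interval algebra and the stringent derived tracks.

test_that("subtract_intervals handles identity, full and partial subtraction", {
  a <- gr1(0, 100)
  expect_equal(plateletTx:::.gr0(subtract_intervals(a, GenomicRanges::GRanges()))[, c("start", "end")],
               data.frame(start = 0, end = 100))
  expect_length(subtract_intervals(a, gr1(0, 100)), 0)

  # per-base enumeration oracle for a = [0,100), b = {[10,20),[50,120)}
  b <- gr1(c(10, 50), c(20, 120))
  got <- plateletTx:::.gr0(subtract_intervals(a, b))
  want <- mask_to_intervals(base_mask(0, 100, 200) &
                              !base_mask(c(10, 50), c(20, 120), 200))
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("subtract_intervals rejects mixed chromosomes and is idempotent", {
  a <- gr1(0, 100)
  b <- gr1(10, 20, chrom = "chr2")
  expect_error(subtract_intervals(a, b), "chromosome")

  set.seed(7)
  for (i in 1:20) {
    x <- gr1(sample(0:500, 5), sample(501:1000, 5))
    y <- gr1(sample(0:500, 4), sample(501:1000, 4))
    once <- subtract_intervals(x, y)
    twice <- subtract_intervals(once, y)
    expect_equal(plateletTx:::.gr0(twice), plateletTx:::.gr0(once))
  }
})

test_that("purely intronic derivation follows the sense-only rule", {
  # gene [0,1000)+ with terminal exons; a sense ncRNA punches a hole in the
  # intron, an antisense repeat does not
  g <- gr1(0, 1000, "+", id = "G1")
  e <- gr1(c(0, 900), c(100, 1000), "+",
           id = c("G1_e1", "G1_e2"))
  S4Vectors::mcols(e)$gene_id <- c("G1", "G1")
  sense <- gr1(200, 210, "+", id = "snRNA1")
  b <- annotation_bundle(c(chr1 = 1000),
                         list(protein_coding_gene_span = g,
                              protein_coding_exon = e,
                              snRNA = sense))
  got <- plateletTx:::.gr0(derive_purely_intronic(b))
  expect_equal(got$start, c(100, 210))
  expect_equal(got$end, c(200, 900))
  expect_true(all(got$strand == "+"))

  # antisense repeat inside the intron leaves it untouched
  b2 <- annotation_bundle(c(chr1 = 1000),
                          list(protein_coding_gene_span = g,
                               protein_coding_exon = e,
                               SINE = gr1(300, 400, "-", id = "S1")))
  got2 <- plateletTx:::.gr0(derive_purely_intronic(b2))
  expect_equal(got2$start, 100)
  expect_equal(got2$end, 900)

  # unstranded feature is conservatively sense to both strands
  b3 <- annotation_bundle(c(chr1 = 1000),
                          list(protein_coding_gene_span = g,
                               protein_coding_exon = e,
                               SINE = gr1(300, 400, "*", id = "S1")))
  got3 <- plateletTx:::.gr0(derive_purely_intronic(b3))
  expect_equal(got3$start, c(100, 400))
  expect_equal(got3$end, c(300, 900))
})

test_that("single-exon genes yield no intronic track and bad exons error", {
  g <- gr1(0, 500, "+", id = "G1")
  e <- gr1(0, 500, "+", id = "G1_e1")
  S4Vectors::mcols(e)$gene_id <- "G1"
  b <- annotation_bundle(c(chr1 = 600),
                         list(protein_coding_gene_span = g,
                              protein_coding_exon = e))
  expect_length(derive_purely_intronic(b), 0)

  e2 <- gr1(c(0, 550), c(100, 590), "+", id = c("e1", "e2"))
  S4Vectors::mcols(e2)$gene_id <- c("G1", "G1")
  b2 <- annotation_bundle(c(chr1 = 600),
                          list(protein_coding_gene_span = g,
                               protein_coding_exon = e2))
  expect_error(derive_purely_intronic(b2), "outside its span")
})

test_that("unannotated intergenic derivation is the strand-blind complement", {
  feats <- gr1(c(0, 900), c(100, 1000), c("+", "-"), id = c("A", "B"))
  b <- annotation_bundle(c(chr1 = 1000), list(SINE = feats))
  got <- plateletTx:::.gr0(derive_unannotated_intergenic(b))
  expect_equal(got$start, 100)
  expect_equal(got$end, 900)

  b0 <- annotation_bundle(c(chr1 = 1000), list())
  got0 <- plateletTx:::.gr0(derive_unannotated_intergenic(b0))
  expect_equal(got0$start, 0)
  expect_equal(got0$end, 1000)

  bf <- annotation_bundle(c(chr1 = 1000), list(SINE = gr1(0, 1000, id = "S")))
  expect_length(derive_unannotated_intergenic(bf), 0)
})

test_that("derived tracks match the per-base oracle on random toy genomes", {
  set.seed(42)
  for (i in 1:30) {
    b <- random_toy_bundle(max_len = 2e4)
    pi_gr <- derive_purely_intronic(b)
    for (s in c("+", "-")) {
      got <- mask_of(pi_gr[as.character(GenomicRanges::strand(pi_gr)) == s],
                     "chr1", b$genome[["chr1"]])
      expect_equal(got, oracle_purely_intronic(b, "chr1", s))
    }
    ig_gr <- derive_unannotated_intergenic(b)
    expect_equal(mask_of(ig_gr, "chr1", b$genome[["chr1"]]),
                 oracle_intergenic(b, "chr1"))
  }
})

test_that("derived tracks are base-level disjoint from what was subtracted", {
  b <- make_genome(cohort_config(n_genes = 40, n_pseudogenes = 10,
                                 n_lncRNA = 8, n_repeats_per_class = 4,
                                 seed = 5))
  pi_gr <- b$tracks$purely_intronic
  ig_gr <- b$tracks$unannotated_intergenic
  for (chrom in names(b$genome)) {
    len <- b$genome[[chrom]]
    # intergenic vs everything annotated
    ann <- logical(len)
    for (cat_ in setdiff(names(b$tracks), feature_categories("derived")))
      ann <- ann | mask_of(b$tracks[[cat_]], chrom, len)
    expect_false(any(mask_of(ig_gr, chrom, len) & ann))
    # purely intronic vs exons and same-strand features
    for (s in c("+", "-")) {
      pim <- mask_of(pi_gr[as.character(GenomicRanges::strand(pi_gr)) == s],
                     chrom, len)
      for (cat_ in setdiff(names(b$tracks),
                           c("protein_coding_gene_span",
                             feature_categories("derived")))) {
        tr <- b$tracks[[cat_]]
        sel <- as.character(GenomicRanges::strand(tr)) %in% c(s, "*")
        expect_false(any(pim & mask_of(tr[sel], chrom, len)))
      }
    }
  }
})

test_that("bundle validation enforces vocabulary and bounds", {
  expect_error(annotation_bundle(c(chr1 = 100), list(bogus = gr1(0, 10))),
               "unknown annotation categories")
  expect_error(annotation_bundle(c(chr1 = 100),
                                 list(SINE = gr1(50, 150, id = "S"))),
               "beyond chromosome bounds")
  expect_error(annotation_bundle(c(chr1 = 100),
                                 list(SINE = gr1(c(0, 5), c(10, 20),
                                                 id = c("S", "S")))),
               "duplicated feature_id")
})
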