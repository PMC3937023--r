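# Brute-force per-base oracles and toy-genome builders used across tests.
# The oracles are deliberately naive (logical vectors over every base) and
# independent of the package's interval algebra.

gr1 <- function(start0, end0, strand = "*", chrom = "chr1", id = NULL) {
  plateletTx:::.gr(chrom, start0, end0, strand = strand, feature_id = id)
}

# per-base membership vector of a set of 0-based intervals on one chromosome
base_mask <- function(starts0, ends0, len) {
  v <- logical(len)
  for (i in seq_along(starts0)) {
    if (ends0[i] > starts0[i])
      v[(starts0[i] + 1):ends0[i]] <- TRUE
  }
  v
}

mask_of <- function(gr, chrom, len) {
  sel <- as.character(GenomicRanges::seqnames(gr)) == chrom
  base_mask(GenomicRanges::start(gr)[sel] - 1, GenomicRanges::end(gr)[sel],
            len)
}

# mask -> sorted 0-based half-open intervals
mask_to_intervals <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  data.frame(start = starts[r$values], end = ends[r$values])
}

# per-base oracle for the purely-intronic derivation, one chromosome/strand:
# a base is purely intronic on strand s iff some gene on s contains it in its
# span, outside that gene's exons, and no non-gene-span feature on strand s
# or "*" covers it
oracle_purely_intronic <- function(bundle, chrom, strand) {
  len <- bundle$genome[[chrom]]
  genes <- bundle$tracks$protein_coding_gene_span
  exons <- bundle$tracks$protein_coding_exon
  sel_g <- as.character(GenomicRanges::seqnames(genes)) == chrom &
    as.character(GenomicRanges::strand(genes)) == strand
  acc <- logical(len)
  for (i in which(sel_g)) {
    g <- genes[i]
    gid <- S4Vectors::mcols(g)$feature_id
    span <- base_mask(GenomicRanges::start(g) - 1, GenomicRanges::end(g), len)
    own <- exons[S4Vectors::mcols(exons)$gene_id == gid &
                   as.character(GenomicRanges::seqnames(exons)) == chrom]
    exm <- if (length(own))
      base_mask(GenomicRanges::start(own) - 1, GenomicRanges::end(own), len)
    else logical(len)
    acc <- acc | (span & !exm)
  }
  pool <- logical(len)
  for (cat_ in setdiff(names(bundle$tracks),
                       c("protein_coding_gene_span",
                         feature_categories("derived")))) {
    tr <- bundle$tracks[[cat_]]
    sel <- as.character(GenomicRanges::seqnames(tr)) == chrom &
      as.character(GenomicRanges::strand(tr)) %in% c(strand, "*")
    if (any(sel))
      pool <- pool | base_mask(GenomicRanges::start(tr)[sel] - 1,
                               GenomicRanges::end(tr)[sel], len)
  }
  acc & !pool
}

# per-base oracle for the unannotated-intergenic derivation (strand-blind)
oracle_intergenic <- function(bundle, chrom) {
  len <- bundle$genome[[chrom]]
  covered <- logical(len)
  for (cat_ in setdiff(names(bundle$tracks), feature_categories("derived"))) {
    tr <- bundle$tracks[[cat_]]
    sel <- as.character(GenomicRanges::seqnames(tr)) == chrom
    if (any(sel))
      covered <- covered | base_mask(GenomicRanges::start(tr)[sel] - 1,
                                     GenomicRanges::end(tr)[sel], len)
  }
  !covered
}

# random toy genome (single chromosome, <= max_len bases) with overlapping
# gene models, intra-intron features and unstranded repeats
random_toy_bundle <- function(max_len = 1e5, n_genes = 8, n_feats = 25) {
  len <- sample(2000:max_len, 1)
  genes <- list(); exons <- list()
  for (i in seq_len(n_genes)) {
    gs <- sample(0:(len - 600), 1)
    ge <- min(len, gs + sample(300:3000, 1))
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("G%03d", i)
    n_ex <- sample(1:4, 1)
    cuts <- sort(sample(gs:(ge - 1), 2 * n_ex))
    es <- cuts[seq(1, 2 * n_ex, 2)]
    ee <- pmax(es + 1, cuts[seq(2, 2 * n_ex, 2)])
    # force hull coverage so exons stay inside the span
    genes[[i]] <- data.frame(start = gs, end = ge, strand = strand, id = gid)
    exons[[i]] <- data.frame(start = es, end = ee, strand = strand, gid = gid)
  }
  gdf <- do.call(rbind, genes)
  edf <- do.call(rbind, exons)
  g_gr <- gr1(gdf$start, gdf$end, gdf$strand, id = gdf$id)
  e_gr <- gr1(edf$start, edf$end, edf$strand,
              id = sprintf("E%03d", seq_len(nrow(edf))))
  S4Vectors::mcols(e_gr)$gene_id <- edf$gid
  cls <- sample(c("SINE", "LINE", "rRNA", "snRNA", "pseudogene", "lncRNA"),
                n_feats, replace = TRUE)
  fs <- sample(0:(len - 200), n_feats)
  fe <- pmin(len, fs + sample(20:500, n_feats, replace = TRUE))
  fstr <- sample(c("+", "-", "*"), n_feats, replace = TRUE)
  tracks <- list(protein_coding_gene_span = g_gr, protein_coding_exon = e_gr)
  for (cl in unique(cls)) {
    sel <- cls == cl
    tracks[[cl]] <- gr1(fs[sel], fe[sel], fstr[sel],
                        id = sprintf("%s%03d", cl, which(sel)))
  }
  annotation_bundle(c(chr1 = len), tracks)
}

# tiny ExpressionMatrix builder: values matrix with a constant reference row
toy_em <- function(values, reference = 1e4, threshold = 1e-4,
                   gene_category = NULL) {
  ref <- matrix(reference, 1, ncol(values),
                dimnames = list("ENST00000331789", colnames(values)))
  v <- rbind(ref, values)
  expression_matrix(v, reference_id = "ENST00000331789",
                    threshold = threshold,
                    gene_category = if (is.null(gene_category)) NULL else
                      c("mRNA", gene_category))
}
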