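# Seeded synthetic-data generation: toy genomes, cohort read sets,
# matrix-level expression cohorts, microarray mirrors and quantitative
# proteomes with the statistical structure the analysis pipeline assumes.

#' Cohort simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: 10
#' individuals in two donor groups of five; a read-category mix of 43\%
#' exon, 36.6\% rRNA, 14\% unannotated intergenic and 6\% other loci; a
#' log-normal shared mRNA abundance profile (location 0, log-scale sd 2)
#' with small per-individual noise so inter-individual Pearson correlations
#' are high; and group-specific pseudogene profiles that are uncorrelated
#' between groups (\code{pseudogene_group_divergence = 0}).  Reads are 50 nt.
#'
#' @param n_individuals Number of donors (default 10).
#' @param groups Group label per donor (default five \code{"W"} then five
#'   \code{"B"}).
#' @param n_genes,n_pseudogenes,n_lncRNA Feature counts for the toy genome.
#' @param n_repeats_per_class Features per RepeatMasker class (default 25).
#' @param category_mix Named target read fractions; must sum to at most 1,
#'   any remainder goes to purely intronic reads.
#' @param abundance_meanlog,abundance_sdlog Log-normal (natural log) shared
#'   mRNA profile parameters.
#' @param individual_noise_sd Per-individual log-scale noise sd.
#' @param pseudogene_group_divergence Correlation between the two groups'
#'   pseudogene log-profiles (0 = independent).
#' @param reads_per_sample Uniquely mapped reads simulated per donor.
#' @param read_length Read length in nt (default 50).
#' @param chrom_lengths Optional named chromosome lengths; features are laid
#'   out sequentially and an error is raised if they do not fit.  Default
#'   \code{NULL} sizes chromosomes to the layout.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A \code{CohortConfig} list.
#' @export
cohort_config <- function(n_individuals = 10,
                          groups = rep(c("W", "B"), each = 5),
                          n_genes = 300, n_pseudogenes = 60, n_lncRNA = 40,
                          n_repeats_per_class = 25,
                          category_mix = c(protein_coding_exon = 0.43,
                                           rRNA = 0.366,
                                           unannotated_intergenic = 0.14,
                                           other = 0.06),
                          abundance_meanlog = 0, abundance_sdlog = 2,
                          individual_noise_sd = 0.25,
                          pseudogene_group_divergence = 0,
                          reads_per_sample = 50000, read_length = 50,
                          chrom_lengths = NULL, seed = 1) {
  if (length(groups) != n_individuals)
    stop("groups must have one label per individual")
  if (sum(category_mix) > 1 + 1e-9)
    stop("category_mix must sum to at most 1")
  if (any(c(n_genes, n_pseudogenes, reads_per_sample) <= 0))
    stop("counts must be positive")
  structure(list(n_individuals = n_individuals, groups = groups,
                 n_genes = n_genes, n_pseudogenes = n_pseudogenes,
                 n_lncRNA = n_lncRNA,
                 n_repeats_per_class = n_repeats_per_class,
                 category_mix = category_mix,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 individual_noise_sd = individual_noise_sd,
                 pseudogene_group_divergence = pseudogene_group_divergence,
                 reads_per_sample = reads_per_sample,
                 read_length = read_length,
                 chrom_lengths = chrom_lengths, seed = seed),
            class = "CohortConfig")
}

#' Simulate a toy annotated genome
#'
#' Lays out multi-exon genes (2-5 exons, introns included), pseudogenes,
#' lncRNAs and the 14 repeat/ncRNA classes sequentially over two
#' chromosomes, separated by guaranteed unannotated gaps.  About a third of
#' multi-exon genes additionally receive a repeat inside one of their
#' introns (random strand), so the purely-intronic derivation has sense and
#' antisense cases to resolve.  The first gene is designated the beta-actin
#' reference and carries the id \code{ENST00000331789}.
#'
#' @param config A \code{CohortConfig}.
#' @return An \code{AnnotationBundle} including derived tracks.
#' @export
make_genome <- function(config = cohort_config()) {
  set.seed(config$seed)
  rl <- function(n, lo, hi) sample(lo:hi, n, replace = TRUE)

  # build the queue of loci to place
  repeat_classes <- feature_categories("repeat")
  queue <- c(rep("gene", config$n_genes),
             rep("pseudogene", config$n_pseudogenes),
             rep("lncRNA", config$n_lncRNA),
             rep(repeat_classes, each = config$n_repeats_per_class))
  queue <- sample(queue)
  # the reference gene is always placed first so it exists on chr1
  queue <- c("gene", queue[-match("gene", queue)])

  chroms <- c("chr1", "chr2")
  chrom_of <- rep(chroms, length.out = length(queue))
  cursor <- setNames(numeric(2), chroms)

  feats <- list()  # rows: chrom, start, end, strand, category, feature_id, gene_id
  add <- function(chrom, start, end, strand, category, fid, gid = NA) {
    feats[[length(feats) + 1L]] <<- list(chrom = chrom, start = start,
                                         end = end, strand = strand,
                                         category = category,
                                         feature_id = fid, gene_id = gid)
  }

  counters <- new.env()
  next_id <- function(prefix) {
    n <- (get0(prefix, counters, ifnotfound = 0L)) + 1L
    assign(prefix, n, counters)
    sprintf("%s%04d", prefix, n)
  }

  gene_no <- 0L
  for (i in seq_along(queue)) {
    kind <- queue[i]
    chrom <- chrom_of[i]
    pos <- cursor[[chrom]] + rl(1, 300, 2000)
    strand <- sample(c("+", "-"), 1)
    if (kind == "gene") {
      gene_no <- gene_no + 1L
      gid <- if (gene_no == 1L) "ENST00000331789" else next_id("G")
      n_ex <- rl(1, 2, 5)
      ex_len <- rl(n_ex, 100, 400)
      in_len <- if (n_ex > 1) rl(n_ex - 1, 300, 1500) else integer(0)
      ex_start <- pos + c(0, cumsum(ex_len[-n_ex] + in_len))
      ex_end <- ex_start + ex_len
      span_end <- ex_end[n_ex]
      add(chrom, pos, span_end, strand, "protein_coding_gene_span", gid)
      for (e in seq_len(n_ex))
        add(chrom, ex_start[e], ex_end[e], strand, "protein_coding_exon",
            sprintf("%s_exon%02d", gid, e), gid)
      # occasionally drop a repeat inside an intron (sense or antisense)
      if (n_ex > 1 && runif(1) < 0.35) {
        k <- rl(1, 1, n_ex - 1)
        ist <- ex_end[k]; ien <- ex_start[k + 1]
        if (ien - ist > 120) {
          w <- rl(1, 60, min(300, ien - ist - 40))
          s0 <- ist + rl(1, 10, ien - ist - w - 10)
          cls <- sample(repeat_classes, 1)
          add(chrom, s0, s0 + w, sample(c("+", "-", "*"), 1), cls,
              next_id(paste0(cls, "_i")))
        }
      }
      cursor[[chrom]] <- span_end
    } else {
      w <- switch(kind,
                  pseudogene = rl(1, 400, 2000),
                  lncRNA = rl(1, 300, 3000),
                  rRNA = rl(1, 1000, 5000),
                  rl(1, 150, 800))
      if (kind %in% c("Simple_repeat", "Satellite", "DNA", "SINE", "LINE",
                      "LTR", "RC", "Other") && runif(1) < 0.5)
        strand <- "*"
      fid <- next_id(paste0(sub("^(pseudogene)$", "PG",
                                sub("^(lncRNA)$", "LNC", kind)), "_"))
      add(chrom, pos, pos + w, strand, kind, fid)
      cursor[[chrom]] <- pos + w
    }
  }

  df <- data.frame(
    chrom = vapply(feats, `[[`, "", "chrom"),
    start = vapply(feats, `[[`, 0, "start"),
    end = vapply(feats, `[[`, 0, "end"),
    strand = vapply(feats, `[[`, "", "strand"),
    category = vapply(feats, `[[`, "", "category"),
    feature_id = vapply(feats, `[[`, "", "feature_id"),
    gene_id = vapply(feats, function(f) as.character(f$gene_id), ""),
    stringsAsFactors = FALSE)
  genome <- cursor + rl(2, 1000, 3000)
  if (!is.null(config$chrom_lengths)) {
    want <- config$chrom_lengths[chroms]
    if (any(is.na(want)) || any(cursor > want))
      stop("infeasible packing: features do not fit the requested ",
           "chromosome lengths")
    genome <- setNames(as.numeric(want), chroms)
  }

  tracks <- lapply(split(df, df$category), function(d) {
    gr <- .gr(d$chrom, d$start, d$end, strand = d$strand,
              feature_id = d$feature_id)
    if (d$category[1] == "protein_coding_exon") mcols(gr)$gene_id <- d$gene_id
    GenomicRanges::sort(gr, ignore.strand = TRUE)
  })
  bundle <- annotation_bundle(genome, tracks)
  add_derived_tracks(bundle)
}

# internal: shared and group-specific log-abundance profiles for a cohort
# (natural-log scale); the reference gene sits above the rest of the profile
.cohort_profiles <- function(config, gene_ids, pseudo_ids) {
  shared <- rnorm(length(gene_ids), config$abundance_meanlog,
                  config$abundance_sdlog)
  names(shared) <- gene_ids
  ref <- "ENST00000331789"
  if (ref %in% gene_ids) shared[ref] <- max(shared) + 1
  d <- config$pseudogene_group_divergence
  pw <- rnorm(length(pseudo_ids), config$abundance_meanlog,
              config$abundance_sdlog)
  pb <- d * pw + sqrt(1 - d^2) *
    rnorm(length(pseudo_ids), config$abundance_meanlog,
          config$abundance_sdlog)
  names(pw) <- names(pb) <- pseudo_ids
  list(mrna = shared, pseudogene = list(W = pw, B = pb))
}

#' Simulate per-individual mapped read sets
#'
#' Draws each donor's reads over the annotation categories according to the
#' configured mix (multinomial); within mRNA, reads land on exons with
#' probability proportional to \code{exp(shared log-profile +
#' individual noise)} times exon length share; pseudogene reads use the
#' donor group's profile; all other categories pick a feature proportional
#' to its length.  Read positions are uniform within the chosen feature and
#' lengths are fixed (50 nt by default, clipped to short features).
#'
#' @param bundle \code{AnnotationBundle} from \code{\link{make_genome}}
#'   (derived tracks required for intronic/intergenic reads).
#' @param config The \code{CohortConfig} used to build the bundle.
#' @return Named list of \code{GRanges} (one per donor, \code{S01} ...),
#'   with the donor group labels in attribute \code{groups} and the planted
#'   profiles in attribute \code{profiles}.
#' @export
simulate_read_sets <- function(bundle, config = cohort_config()) {
  if (config$reads_per_sample <= 0) stop("zero reads requested")
  if (is.null(bundle$tracks$unannotated_intergenic))
    bundle <- add_derived_tracks(bundle)
  set.seed(config$seed + 1L)

  genes <- bundle$tracks$protein_coding_gene_span
  exons <- bundle$tracks$protein_coding_exon
  pseudo <- bundle$tracks$pseudogene
  gene_ids <- mcols(genes)$feature_id
  pseudo_ids <- mcols(pseudo)$feature_id
  prof <- .cohort_profiles(config, gene_ids, pseudo_ids)

  # expand the configured mix over concrete categories
  mix <- config$category_mix
  other <- if ("other" %in% names(mix)) mix[["other"]] else 0
  probs <- mix[setdiff(names(mix), "other")]
  if (other > 0) {
    oth <- c(pseudogene = 0.5 * other, lncRNA = 0.1 * other)
    rep_cls <- setdiff(feature_categories("repeat"), "rRNA")
    rep_cls <- rep_cls[vapply(bundle$tracks[rep_cls],
                              function(g) !is.null(g) && length(g) > 0,
                              TRUE)]
    oth <- c(oth, setNames(rep(0.4 * other / length(rep_cls),
                               length(rep_cls)), rep_cls))
    probs <- c(probs, oth)
  }
  rem <- 1 - sum(probs)
  if (rem > 1e-9) probs <- c(probs, purely_intronic = rem)

  exon_gene <- mcols(exons)$gene_id
  exon_w <- GenomicRanges::width(exons)
  exonic_len <- tapply(exon_w, exon_gene, sum)

  draw_in_feature <- function(track_gr, idx, rl) {
    d <- .gr0(track_gr[idx])
    w <- d$end - d$start
    rlen <- pmin(rl, w)
    s0 <- d$start + floor(runif(length(idx)) * (w - rlen + 1))
    strand <- ifelse(d$strand == "*", "+", d$strand)
    .gr(d$chrom, s0, s0 + rlen, strand = strand)
  }

  out <- vector("list", config$n_individuals)
  names(out) <- sprintf("S%02d", seq_len(config$n_individuals))
  for (i in seq_len(config$n_individuals)) {
    counts <- as.vector(stats::rmultinom(1, config$reads_per_sample, probs))
    names(counts) <- names(probs)
    pieces <- list()
    for (cat_ in names(counts)) {
      nct <- counts[[cat_]]
      if (nct == 0) next
      if (cat_ == "protein_coding_exon") {
        noise <- rnorm(length(gene_ids), 0, config$individual_noise_sd)
        gw <- exp(prof$mrna + noise)
        # exon-level weights: gene weight split over exons by length
        ew <- gw[exon_gene] * exon_w / exonic_len[exon_gene]
        idx <- sample.int(length(exons), nct, replace = TRUE, prob = ew)
        pieces[[cat_]] <- draw_in_feature(exons, idx, config$read_length)
      } else if (cat_ == "pseudogene") {
        noise <- rnorm(length(pseudo_ids), 0, config$individual_noise_sd)
        pw <- exp(prof$pseudogene[[config$groups[i]]] + noise)
        idx <- sample.int(length(pseudo), nct, replace = TRUE, prob = pw)
        pieces[[cat_]] <- draw_in_feature(pseudo, idx, config$read_length)
      } else {
        track <- bundle$tracks[[cat_]]
        if (is.null(track) || !length(track))
          stop("no features available for category ", cat_)
        idx <- sample.int(length(track), nct, replace = TRUE,
                          prob = GenomicRanges::width(track))
        pieces[[cat_]] <- draw_in_feature(track, idx, config$read_length)
      }
    }
    reads <- suppressWarnings(do.call(c, unname(pieces)))
    reads <- reads[sample.int(length(reads))]
    mcols(reads)$read_id <- sprintf("%s_%07d", names(out)[i],
                                    seq_along(reads))
    out[[i]] <- reads
  }
  attr(out, "groups") <- setNames(config$groups, names(out))
  attr(out, "profiles") <- prof
  out
}

#' Simulate a matrix-level expression cohort
#'
#' Generates the abundance structure of the cohort directly on the RPKM
#' scale, without a genome: a shared log-normal mRNA profile with
#' per-individual noise, group-specific pseudogene profiles, and a constant
#' highly-expressed beta-actin reference whose abundance places the
#' 1/10,000 call threshold at the centre of the mRNA profile (so a
#' realistic share of genes is expressed in all, some, or none of the
#' donors).  Used for analyses that operate on matrices (correlation
#' structure, proteome concordance) at gene counts far beyond what a toy
#' genome carries.
#'
#' @param n_genes,n_pseudogenes Row counts (defaults 36000 / 500; a
#'   genome-scale gene universe so the expressed all-donor and
#'   partial-sharing subsets reach the observed thousands with headroom for
#'   downstream allocation).
#' @param groups Group label per sample.
#' @param abundance_meanlog,abundance_sdlog,individual_noise_sd,
#'   pseudogene_group_divergence As in \code{\link{cohort_config}}.
#' @param reference_abundance Constant reference value (default \code{1e4},
#'   placing the \code{1e-4} ratio threshold at the profile median).
#' @param threshold Expression-ratio cutoff for calls.
#' @param seed Integer seed.
#' @return An \code{ExpressionMatrix} with \code{gene_category} metadata
#'   (\code{"mRNA"} / \code{"pseudogene"}) and sample groups in attribute
#'   \code{groups}.
#' @export
simulate_expression_cohort <- function(n_genes = 36000, n_pseudogenes = 500,
                                       groups = rep(c("W", "B"), each = 5),
                                       abundance_meanlog = 0,
                                       abundance_sdlog = 2,
                                       individual_noise_sd = 0.25,
                                       pseudogene_group_divergence = 0,
                                       reference_abundance = 1e4,
                                       threshold = 1e-4, seed = 1) {
  set.seed(seed)
  ns <- length(groups)
  gene_ids <- c("ENST00000331789", sprintf("G%05d", seq_len(n_genes - 1)))
  pseudo_ids <- sprintf("PG%05d", seq_len(n_pseudogenes))
  cfg <- list(abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              pseudogene_group_divergence = pseudogene_group_divergence)
  prof <- .cohort_profiles(cfg, gene_ids, pseudo_ids)

  vals <- matrix(0, n_genes + n_pseudogenes, ns,
                 dimnames = list(c(gene_ids, pseudo_ids),
                                 sprintf("S%02d", seq_len(ns))))
  for (i in seq_len(ns)) {
    g <- exp(prof$mrna + rnorm(n_genes, 0, individual_noise_sd))
    p <- exp(prof$pseudogene[[groups[i]]] +
               rnorm(n_pseudogenes, 0, individual_noise_sd))
    vals[, i] <- c(g, p)
  }
  vals["ENST00000331789", ] <- reference_abundance
  em <- expression_matrix(vals, reference_id = "ENST00000331789",
                          threshold = threshold,
                          gene_category = c(rep("mRNA", n_genes),
                                            rep("pseudogene",
                                                n_pseudogenes)))
  attr(em, "groups") <- setNames(groups, colnames(vals))
  em
}

#' Simulate a microarray mirror of an expression cohort
#'
#' Produces an RMA-style log2 matrix as an affine monotone transform of the
#' normalized RNA-seq abundances plus Gaussian measurement noise, so
#' intra-individual cross-platform rank correlations are high but not
#' perfect.
#'
#' @param em \code{ExpressionMatrix} for the RNA-seq arm.
#' @param noise_sd Measurement noise sd on the log2 scale (default 0.5).
#' @param seed Optional integer seed.
#' @return Numeric genes-by-samples matrix (log2 scale).
#' @export
simulate_microarray <- function(em, noise_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- log2(em$normalized + 1e-6)
  out <- 8 + 0.6 * base + matrix(rnorm(length(base), 0, noise_sd),
                                 nrow(base), ncol(base))
  dimnames(out) <- dimnames(em$normalized)
  out
}

#' Proteome simulation configuration
#'
#' Defaults mirror the five-way partition sizes of the reference proteome
#' comparison: 2,338 proteins paired with transcripts present in all 10
#' donors, 432 proteins with no transcript, 774 proteins paired with
#' transcripts present in 1-9 donors, 3,226 all-donor transcripts without a
#' protein and 3,634 partial-sharing transcripts without a protein.  The
#' Gaussian-copula correlation for the overlapping pairs defaults to
#' \code{2 * sin(0.311 * pi / 6) = 0.3242}, the value whose closed-form
#' Spearman \code{(6 / pi) * asin(rho / 2)} equals the observed rank
#' concordance of 0.311.
#'
#' @param n_overlap_pairs Proteins paired with all-donor transcripts.
#' @param n_protein_only Proteins with no cognate transcript.
#' @param n_mrna_only_all All-donor transcripts without a protein.
#' @param n_overlap_1to9 Proteins paired with partial-sharing transcripts.
#' @param n_mrna_only_1to9 Partial-sharing transcripts without a protein.
#' @param copula_rho Gaussian-copula correlation for overlapping pairs.
#' @param n_low_confidence,n_duplicates Decoy entries (confidence below
#'   99\%, and duplicate ids at lower abundance) added so the confidence and
#'   duplicate filters have work to do.
#' @param seed Optional integer seed.
#' @return A \code{ProteomeSimConfig} list.
#' @export
proteome_sim_config <- function(n_overlap_pairs = 2338, n_protein_only = 432,
                                n_mrna_only_all = 3226,
                                n_overlap_1to9 = 774,
                                n_mrna_only_1to9 = 3634,
                                copula_rho = 2 * sin(0.311 * pi / 6),
                                n_low_confidence = 300, n_duplicates = 200,
                                seed = NULL) {
  if (abs(copula_rho) >= 1) stop("copula_rho must be in (-1, 1)")
  counts <- c(n_overlap_pairs, n_protein_only, n_mrna_only_all,
              n_overlap_1to9, n_mrna_only_1to9)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(n_overlap_pairs = n_overlap_pairs,
                 n_protein_only = n_protein_only,
                 n_mrna_only_all = n_mrna_only_all,
                 n_overlap_1to9 = n_overlap_1to9,
                 n_mrna_only_1to9 = n_mrna_only_1to9,
                 copula_rho = copula_rho,
                 n_low_confidence = n_low_confidence,
                 n_duplicates = n_duplicates, seed = seed),
            class = "ProteomeSimConfig")
}

#' Scale a proteome configuration to an expression cohort
#'
#' Rescales the default partition sizes proportionally to the genes the
#' cohort actually provides (all-donor and partial-sharing expressed sets),
#' preserving the default size ratios.  Used when the transcriptome arm is
#' a toy cohort far smaller than the reference comparison.
#'
#' @param em \code{ExpressionMatrix}.
#' @param seed Optional seed stored on the result.
#' @return A \code{ProteomeSimConfig}.
#' @export
scale_proteome_config <- function(em, seed = NULL) {
  k <- rowSums(em$calls)
  n <- ncol(em$calls)
  genes <- setdiff(rownames(em$calls), em$reference_id)
  if (!is.null(em$gene_category))
    genes <- intersect(genes,
                       rownames(em$calls)[em$gene_category == "mRNA"])
  a <- sum(k[genes] == n)
  b <- sum(k[genes] >= 1 & k[genes] < n)
  n_ov <- max(3, round(a * 2338 / 5564))
  n_ov19 <- max(0, round(b * 774 / 4408))
  proteome_sim_config(
    n_overlap_pairs = n_ov,
    n_protein_only = max(1, round(n_ov * 432 / 2338)),
    n_mrna_only_all = a - n_ov,
    n_overlap_1to9 = n_ov19,
    n_mrna_only_1to9 = b - n_ov19,
    n_low_confidence = max(1, round(n_ov * 300 / 2338)),
    n_duplicates = max(1, round(n_ov * 200 / 2338)),
    seed = seed)
}

#' Simulate a quantitative proteome against an expression cohort
#'
#' Allocates the configured gene sets from the cohort's expression calls
#' (all-donor and partial-sharing expressed genes, reference excluded),
#' draws protein abundances for overlapping pairs through a Gaussian copula
#' at \code{copula_rho} against mean transcript abundance (planting a known
#' Spearman concordance of \code{(6 / pi) * asin(copula_rho / 2)}), draws
#' protein-only abundances independently, and emits the proteome table, the
#' gene-to-protein mapping, and decoy entries for the filters.
#'
#' @param em \code{ExpressionMatrix}.
#' @param config A \code{ProteomeSimConfig}; \code{NULL} auto-scales the
#'   defaults to the cohort via \code{\link{scale_proteome_config}}.
#' @return List with \code{proteome} (data.frame incl. decoys),
#'   \code{mapping} (data.frame), \code{expression} (the matched
#'   transcriptome arm: the allocated expressed genes plus all
#'   never-expressed and non-mRNA rows, so the downstream partition
#'   reproduces the configured group sizes), and \code{planted} (the
#'   allocated id sets).
#' @export
simulate_proteome <- function(em, config = proteome_sim_config()) {
  if (is.null(config)) config <- scale_proteome_config(em)
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- rowSums(em$calls)
  n <- ncol(em$calls)
  genes <- setdiff(rownames(em$calls), em$reference_id)
  if (!is.null(em$gene_category))
    genes <- intersect(genes,
                       rownames(em$calls)[em$gene_category == "mRNA"])
  alln <- genes[k[genes] == n]
  part <- genes[k[genes] >= 1 & k[genes] < n]
  need_alln <- config$n_overlap_pairs + config$n_mrna_only_all
  need_part <- config$n_overlap_1to9 + config$n_mrna_only_1to9
  if (length(alln) < need_alln || length(part) < need_part)
    stop("insufficient expressed genes to allocate the requested sets (",
         length(alln), " all-donor available, ", need_alln, " needed; ",
         length(part), " partial available, ", need_part, " needed)")

  alln <- sample(alln, need_alln)
  part <- sample(part, need_part)
  g_ov <- alln[seq_len(config$n_overlap_pairs)]
  g_mo <- alln[-seq_len(config$n_overlap_pairs)]
  g_ov19 <- if (config$n_overlap_1to9 > 0)
    part[seq_len(config$n_overlap_1to9)] else character(0)

  copula_abundance <- function(x, rho) {
    z <- stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
    exp(rho * z + sqrt(1 - rho^2) * rnorm(length(x)))
  }
  tx <- rowMeans(em$normalized)
  rho <- config$copula_rho

  prot_ids <- sprintf("UP%05d",
                      seq_len(config$n_overlap_pairs +
                                config$n_overlap_1to9 +
                                config$n_protein_only))
  id_ov <- prot_ids[seq_along(g_ov)]
  id_ov19 <- prot_ids[length(g_ov) + seq_along(g_ov19)]
  id_only <- prot_ids[length(g_ov) + length(g_ov19) +
                        seq_len(config$n_protein_only)]

  proteome <- data.frame(
    protein_id = c(id_ov, id_ov19, id_only),
    abundance = c(copula_abundance(tx[g_ov], rho),
                  if (length(g_ov19)) copula_abundance(tx[g_ov19], rho)
                  else numeric(0),
                  exp(rnorm(config$n_protein_only))),
    confidence = sample(c(99, 100), length(prot_ids), replace = TRUE),
    stringsAsFactors = FALSE)

  # decoys: sub-confidence entries and lower-abundance duplicates
  if (config$n_low_confidence > 0) {
    proteome <- rbind(proteome, data.frame(
      protein_id = sprintf("LOWCONF%05d", seq_len(config$n_low_confidence)),
      abundance = exp(rnorm(config$n_low_confidence)),
      confidence = sample(50:98, config$n_low_confidence, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  if (config$n_duplicates > 0) {
    dup_of <- sample(seq_along(prot_ids), config$n_duplicates,
                     replace = TRUE)
    proteome <- rbind(proteome, data.frame(
      protein_id = proteome$protein_id[dup_of],
      abundance = proteome$abundance[dup_of] * runif(config$n_duplicates,
                                                     0.1, 0.9),
      confidence = sample(c(99, 100), config$n_duplicates, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  proteome <- proteome[sample.int(nrow(proteome)), , drop = FALSE]
  rownames(proteome) <- NULL

  mapping <- data.frame(gene_id = c(g_ov, g_ov19),
                        protein_id = c(id_ov, id_ov19),
                        stringsAsFactors = FALSE)
  # the matched transcriptome arm: the allocated expressed genes plus every
  # never-expressed gene (and the reference), so the downstream partition
  # reproduces the configured group sizes exactly
  silent <- genes[k[genes] == 0]
  keep <- c(em$reference_id, alln, part, silent,
            setdiff(rownames(em$values), c(genes, em$reference_id)))
  em_sub <- expression_matrix(em$values[keep, , drop = FALSE],
                              reference_id = em$reference_id,
                              threshold = em$threshold,
                              gene_category = if (is.null(em$gene_category))
                                NULL else
                                em$gene_category[match(keep,
                                                       rownames(em$values))])
  list(proteome = proteome, mapping = mapping, expression = em_sub,
       planted = list(overlap_alln = g_ov, mrna_only_alln = g_mo,
                      overlap_1to9 = g_ov19,
                      mrna_only_1to9 = part[!part %in% g_ov19],
                      protein_only = id_only))
}
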