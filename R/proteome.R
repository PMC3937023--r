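# Quantitative proteome filtering, id collapsing, the five-way
# transcriptome/proteome partition, and rank concordance.

#' Filter a quantitative proteome
#'
#' Keeps entries with a reported confidence of 99\% or 100\% and removes
#' duplicate protein ids, retaining the most abundant entry per id
#' (deterministic: ties keep the first occurrence in input order).
#' Idempotent.
#'
#' @param entries data.frame with \code{protein_id}, \code{abundance},
#'   \code{confidence}.
#' @return Filtered data.frame with unique \code{protein_id}s.
#' @export
filter_proteome <- function(entries) {
  if (!nrow(entries)) return(entries)
  if (any(entries$abundance < 0)) stop("negative protein abundance")
  keep <- entries$confidence >= 99
  out <- entries[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  out <- out[order(-out$abundance), , drop = FALSE]
  out <- out[!duplicated(out$protein_id), , drop = FALSE]
  out[order(out$protein_id), , drop = FALSE]
}

#' Collapse a many-to-one gene-to-protein mapping
#'
#' For every protein id, pairs it with the single most abundant of its
#' mapped transcripts; ties are broken by lexicographically smallest gene
#' id.  Genes absent from \code{abundances} are dropped (they have no
#' transcript-side measurement).
#'
#' @param mapping data.frame with \code{gene_id}, \code{protein_id}.
#' @param abundances Named numeric vector of transcript abundances per gene.
#' @return data.frame: \code{protein_id}, \code{gene_id},
#'   \code{transcript_abundance}.
#' @export
collapse_ids <- function(mapping, abundances) {
  m <- mapping[mapping$gene_id %in% names(abundances), , drop = FALSE]
  if (!nrow(m))
    return(data.frame(protein_id = character(), gene_id = character(),
                      transcript_abundance = numeric(),
                      stringsAsFactors = FALSE))
  ab <- abundances[m$gene_id]
  o <- order(m$protein_id, -ab, m$gene_id)
  m <- m[o, , drop = FALSE]
  ab <- ab[o]
  keep <- !duplicated(m$protein_id)
  data.frame(protein_id = m$protein_id[keep], gene_id = m$gene_id[keep],
             transcript_abundance = as.numeric(ab[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Five-way transcriptome/proteome partition
#'
#' Partitions genes and proteins into the five non-overlapping groups: (1)
#' transcript in all n RNA-seq profiles and protein present
#' (\code{both_alln}); (2) transcript in all n profiles, no protein
#' (\code{mrna_alln_no_protein}); (3) protein with no transcript in any
#' profile (\code{protein_no_mrna}); (4) transcript in 1 to n-1 profiles, no
#' protein (\code{mrna_1to9_no_protein}); (5) protein with transcript in 1
#' to n-1 profiles (\code{protein_and_mrna_1to9}).  Protein-side groups (1,
#' 3, 5) partition the filtered proteome.
#'
#' @param calls Logical genes-by-samples matrix (or an
#'   \code{ExpressionMatrix}).
#' @param proteome Filtered proteome data.frame (see
#'   \code{\link{filter_proteome}}).
#' @param mapping data.frame \code{gene_id} to \code{protein_id}; ids in the
#'   mapping unknown to either side are skipped with a warning and counted
#'   in the \code{n_skipped} attribute.
#' @return Named list of id vectors, one per group (genes for
#'   transcript-side groups, protein ids for protein-side groups), with the
#'   paired gene carried in names for groups 1 and 5.
#' @export
partition_groups <- function(calls, proteome, mapping) {
  if (inherits(calls, "ExpressionMatrix")) calls <- calls$calls
  n <- ncol(calls)
  n_expr <- rowSums(calls)
  genes <- rownames(calls)

  known <- mapping$gene_id %in% genes & mapping$protein_id %in%
    proteome$protein_id
  n_skipped <- sum(!known)
  if (n_skipped)
    warning(n_skipped, " mapping row(s) reference unknown ids; skipped")
  map <- mapping[known, , drop = FALSE]

  # per protein: the maximum sharing level among its mapped genes
  best_k <- setNames(rep(0, nrow(proteome)), proteome$protein_id)
  if (nrow(map)) {
    agg <- tapply(n_expr[map$gene_id], map$protein_id, max)
    best_k[names(agg)] <- agg
  }
  prot_alln <- names(best_k)[best_k == n]
  prot_1to9 <- names(best_k)[best_k >= 1 & best_k < n]
  prot_none <- names(best_k)[best_k == 0]

  # gene side: expressed genes with no protein mapping at all
  has_protein <- genes %in% map$gene_id
  gene_alln_noprot <- genes[n_expr == n & !has_protein]
  gene_1to9_noprot <- genes[n_expr >= 1 & n_expr < n & !has_protein]

  out <- list(both_alln = prot_alln,
              mrna_alln_no_protein = gene_alln_noprot,
              protein_no_mrna = prot_none,
              mrna_1to9_no_protein = gene_1to9_noprot,
              protein_and_mrna_1to9 = prot_1to9)
  attr(out, "n_samples") <- n
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Summary percentages of the five-way partition
#'
#' Recomputes the headline proportions from the group sizes: the share of
#' the proteome with a cognate transcript anywhere / in all profiles /
#' nowhere, and the share of transcript-side genes without a protein.
#'
#' @param groups Result of \code{\link{partition_groups}}.
#' @return Named list of counts and percentages.
#' @export
summarize_partition <- function(groups) {
  n1 <- length(groups$both_alln)
  n2 <- length(groups$mrna_alln_no_protein)
  n3 <- length(groups$protein_no_mrna)
  n4 <- length(groups$mrna_1to9_no_protein)
  n5 <- length(groups$protein_and_mrna_1to9)
  proteome_size <- n1 + n3 + n5
  mrna_union <- n1 + n2 + n4 + n5
  list(n_both_alln = n1, n_mrna_alln_no_protein = n2,
       n_protein_no_mrna = n3, n_mrna_1to9_no_protein = n4,
       n_protein_and_mrna_1to9 = n5,
       proteome_size = proteome_size,
       mrna_union_size = mrna_union,
       mrna_alln_size = n1 + n2,
       pct_proteins_with_mrna = 100 * (proteome_size - n3) / proteome_size,
       pct_proteins_no_mrna = 100 * n3 / proteome_size,
       pct_proteins_mrna_alln = 100 * n1 / proteome_size,
       pct_mrna_no_protein = 100 * (n2 + n4) / mrna_union,
       pct_mrna_alln_no_protein = 100 * n2 / (n1 + n2),
       pct_mrna_alln_no_protein_of_union = 100 * n2 / mrna_union)
}

#' Spearman concordance of paired abundances
#'
#' Spearman rank correlation (midrank ties) between transcript and protein
#' abundances with its large-sample p-value (exact permutation p below 10
#' pairs).  A constant vector cannot be ranked usefully; the result is then
#' flagged.
#'
#' @param pairs data.frame with \code{transcript_abundance} and
#'   \code{protein_abundance} columns (>= 3 rows).
#' @return List: \code{rho}, \code{p}, \code{n}, \code{flag} (\code{NULL} or
#'   \code{"constant"}).
#' @export
concordance_spearman <- function(pairs) {
  x <- pairs$transcript_abundance
  y <- pairs$protein_abundance
  if (length(x) < 3) stop("need at least 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                flag = "constant"))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) < 10))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x), flag = NULL)
}

#' Transcriptome-proteome concordance analysis
#'
#' Full proteome arm: filters the proteome, collapses the id mapping onto
#' the most abundant transcript per protein, builds the five-way partition,
#' and computes Spearman concordance for the genes present in all samples
#' and in the proteome (the "overlap" set).  Transcript abundance is the
#' mean normalized expression across samples.
#'
#' @param em \code{ExpressionMatrix} for the RNA-seq arm.
#' @param proteome Raw proteome data.frame (will be filtered).
#' @param mapping Gene-to-protein mapping data.frame.
#' @return A \code{ConcordanceSet}: list with \code{pairs} (overlap set),
#'   \code{groups}, \code{summary}, \code{spearman}.
#' @export
proteome_concordance <- function(em, proteome, mapping) {
  prot <- filter_proteome(proteome)
  calls <- em$calls
  # the partition is over protein-coding genes: drop other feature rows and
  # the beta-actin reference row (a normalization anchor, not a finding)
  keep <- rownames(calls) != em$reference_id
  if (!is.null(em$gene_category)) keep <- keep & em$gene_category == "mRNA"
  groups <- partition_groups(calls[keep, , drop = FALSE], prot, mapping)
  abundance <- rowMeans(em$normalized)
  collapsed <- collapse_ids(mapping, abundance)
  prot_ab <- setNames(prot$abundance, prot$protein_id)
  overlap <- collapsed[collapsed$protein_id %in% groups$both_alln, ,
                       drop = FALSE]
  pairs <- data.frame(gene_id = overlap$gene_id,
                      protein_id = overlap$protein_id,
                      transcript_abundance = overlap$transcript_abundance,
                      protein_abundance = as.numeric(
                        prot_ab[overlap$protein_id]),
                      stringsAsFactors = FALSE, row.names = NULL)
  sp <- if (nrow(pairs) >= 3) concordance_spearman(pairs) else
    list(rho = NA_real_, p = NA_real_, n = nrow(pairs), flag = "too_few")
  structure(list(pairs = pairs, groups = groups,
                 summary = summarize_partition(groups), spearman = sp),
            class = "ConcordanceSet")
}

#' @export
print.ConcordanceSet <- function(x, ...) {
  s <- x$summary
  cat("ConcordanceSet:\n")
  cat(sprintf("  proteome %d = %d (mRNA all-n) + %d (mRNA 1..n-1) + %d (no mRNA)\n",
              s$proteome_size, s$n_both_alln, s$n_protein_and_mrna_1to9,
              s$n_protein_no_mrna))
  cat(sprintf("  transcript-side union %d; no-protein: %d (all-n) + %d (1..n-1)\n",
              s$mrna_union_size, s$n_mrna_alln_no_protein,
              s$n_mrna_1to9_no_protein))
  cat(sprintf("  overlap Spearman rho = %.3f (p = %.3g, n = %d)\n",
              x$spearman$rho, x$spearman$p, x$spearman$n))
  invisible(x)
}
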