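# Read filtering, single-label category assignment, RPKM, beta-actin-anchored
# expression calls, and presence/sharing accounting.

#' Default read-to-category precedence
#'
#' Single-label assignment order used for the category breakdown: exons
#' first, then rRNA, then the remaining gene-like and repeat classes, with
#' the derived intronic and intergenic tracks as fallbacks.  A read is given
#' the first category in this order that it overlaps by at least one base.
#'
#' @return Ordered character vector of categories.
#' @export
default_precedence <- function() {
  c("protein_coding_exon", "rRNA", "pseudogene", "lncRNA",
    "scRNA", "snRNA", "srpRNA", "tRNA", "RNA", "DNA", "LINE", "SINE",
    "LTR", "RC", "Simple_repeat", "Satellite", "Other",
    "purely_intronic", "unannotated_intergenic")
}

#' Filter mapped reads by length
#'
#' Discards mapped reads shorter than \code{min_len} bases (default 16),
#' preserving input order.  The number of removals is recorded in the
#' \code{n_removed} attribute.
#'
#' @param reads \code{GRanges} of mapped reads.
#' @param min_len Minimum retained length in bases (boundary inclusive).
#' @return Filtered \code{GRanges} with attribute \code{n_removed}.
#' @export
filter_reads <- function(reads, min_len = 16) {
  if (min_len < 1) stop("min_len must be >= 1")
  len <- GenomicRanges::width(reads)
  if (any(len <= 0)) stop("negative or zero-length read record")
  keep <- len >= min_len
  out <- reads[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Assign reads to annotation categories
#'
#' Vectorized single-label assignment: each read receives the first category
#' in \code{precedence} whose track it overlaps by at least one base
#' (strand-blind).  Reads overlapping no track fall to the final precedence
#' entry (the unannotated-intergenic fallback).
#'
#' @param reads \code{GRanges} of filtered reads.
#' @param bundle \code{AnnotationBundle} with derived tracks attached.
#' @param precedence Ordered category vector ending in
#'   \code{unannotated_intergenic}.
#' @return Character vector of categories, one per read.
#' @export
assign_read_category <- function(reads, bundle,
                                 precedence = default_precedence()) {
  if (utils::tail(precedence, 1) != "unannotated_intergenic")
    stop("precedence must end with unannotated_intergenic")
  chr <- unique(as.character(GenomicRanges::seqnames(reads)))
  unknown <- setdiff(chr, names(bundle$genome))
  if (length(unknown))
    stop("reads on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  out <- rep(NA_character_, length(reads))
  remaining <- seq_along(reads)
  for (cat_ in precedence) {
    if (!length(remaining)) break
    track <- bundle$tracks[[cat_]]
    if (is.null(track) || !length(track)) next
    hit <- IRanges::overlapsAny(reads[remaining], track,
                                ignore.strand = TRUE)
    out[remaining[hit]] <- cat_
    remaining <- remaining[!hit]
  }
  out[is.na(out)] <- utils::tail(precedence, 1)
  out
}

#' Category breakdown of a read set
#'
#' Counts and percentages of uniquely mapped reads per category; percentages
#' are over the total of the supplied (filtered) read set and sum to 100.
#'
#' @param reads \code{GRanges} of filtered reads.
#' @param bundle \code{AnnotationBundle}.
#' @param precedence Ordered category vector.
#' @return data.frame with columns \code{category}, \code{count},
#'   \code{percent}, ordered by \code{precedence}.
#' @export
category_fractions <- function(reads, bundle,
                               precedence = default_precedence()) {
  if (!length(reads)) stop("empty read set")
  cats <- assign_read_category(reads, bundle, precedence)
  counts <- table(factor(cats, levels = precedence))
  data.frame(category = names(counts),
             count = as.integer(counts),
             percent = 100 * as.integer(counts) / length(reads),
             stringsAsFactors = FALSE)
}

#' Reads per kilobase per million mapped reads
#'
#' \code{RPKM = count / (length/1000 * total_mapped/1e6)}.
#'
#' @param counts Named numeric vector of read counts per feature.
#' @param lengths Named numeric vector of feature lengths in nt (same names).
#' @param total_mapped Total uniquely mapped reads in the sample, after the
#'   length filter.
#' @return Named numeric vector of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths, total_mapped) {
  if (total_mapped <= 0) stop("total_mapped must be positive")
  lengths <- lengths[names(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every feature needs a positive length")
  counts / ((lengths / 1000) * (total_mapped / 1e6))
}

#' Count reads per feature by maximal exon overlap
#'
#' A read counts toward a feature if it overlaps the feature's (exonic) bases
#' by at least one base; a read overlapping several features goes to the one
#' with the larger overlap, ties broken by lexicographically smallest feature
#' id.  Strand-blind.
#'
#' @param reads \code{GRanges} of filtered reads.
#' @param parts \code{GRanges} of feature parts (e.g. exons) with a
#'   \code{feature_id} metadata column naming the owning feature (exons use
#'   their \code{gene_id}).
#' @param ids Optional character vector of all feature ids, so features with
#'   zero reads appear with count 0.
#' @return Named integer vector of read counts per feature id.
#' @export
count_reads_per_feature <- function(reads, parts, ids = NULL) {
  fid <- mcols(parts)$feature_id
  if (is.null(fid)) stop("parts must carry feature_id")
  if (is.null(ids)) ids <- sort(unique(fid))
  counts <- setNames(integer(length(ids)), ids)
  if (!length(reads) || !length(parts)) return(counts)
  ov <- GenomicRanges::findOverlaps(reads, parts, ignore.strand = TRUE)
  if (!length(ov)) return(counts)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(reads)[queryHits(ov)],
    GenomicRanges::ranges(parts)[subjectHits(ov)]))
  rd <- queryHits(ov)
  ft <- fid[subjectHits(ov)]
  # total overlap per read x feature (a feature may contribute several parts)
  o <- order(rd, ft)
  rd <- rd[o]; ft <- ft[o]; w <- w[o]
  n <- length(rd)
  new_grp <- c(TRUE, rd[-1] != rd[-n] | ft[-1] != ft[-n])
  grp <- cumsum(new_grp)
  tot <- as.vector(rowsum(w, grp))
  rd_g <- rd[new_grp]; ft_g <- ft[new_grp]
  o2 <- order(rd_g, -tot, ft_g)
  best <- ft_g[o2][!duplicated(rd_g[o2])]
  tab <- table(best)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Union-of-exons feature lengths
#'
#' @param parts \code{GRanges} of parts with \code{feature_id} naming the
#'   owning feature.
#' @return Named numeric vector: total non-redundant bases per feature.
#' @export
feature_lengths <- function(parts) {
  fid <- mcols(parts)$feature_id
  by <- split(GenomicRanges::ranges(parts), fid)
  vapply(by, function(r) sum(IRanges::width(IRanges::reduce(r))), numeric(1))
}

# ---- expression matrix ------------------------------------------------------

#' Build an expression matrix with reference-anchored calls
#'
#' Wraps a genes-by-samples abundance matrix (RPKM for the RNA-seq arm) and
#' derives, per sample, the ratio of each gene to the beta-actin reference
#' transcript together with boolean expression calls at the
#' \code{ratio >= threshold} rule (inclusive; the default threshold 1e-4 is
#' the 1/10,000-of-beta-actin cutoff, about 13 PCR cycles).
#'
#' @param values Numeric genes-by-samples matrix with gene-id rownames.
#' @param reference_id Reference transcript id; default the beta-actin
#'   transcript \code{ENST00000331789}.
#' @param threshold Expression-ratio cutoff, default \code{1e-4}.
#' @param gene_category Optional character vector (per row) of feature
#'   categories, e.g. \code{"mRNA"} or \code{"pseudogene"}.
#' @return An object of class \code{ExpressionMatrix}: list with
#'   \code{values}, \code{normalized}, \code{calls}, \code{reference_id},
#'   \code{threshold}, \code{gene_category}.
#' @export
expression_matrix <- function(values, reference_id = "ENST00000331789",
                              threshold = 1e-4, gene_category = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (!reference_id %in% rownames(values))
    stop("reference gene '", reference_id, "' absent from the matrix")
  ref <- values[reference_id, ]
  bad <- colnames(values)[!(is.finite(ref) & ref > 0)]
  if (length(bad))
    stop("reference gene '", reference_id,
         "' has non-positive abundance in sample(s): ",
         paste(bad, collapse = ", "))
  normalized <- sweep(values, 2, ref, "/")
  calls <- normalized >= threshold
  structure(list(values = values, normalized = normalized, calls = calls,
                 reference_id = reference_id, threshold = threshold,
                 gene_category = gene_category),
            class = "ExpressionMatrix")
}

#' Re-derive normalization and calls on an ExpressionMatrix
#'
#' @param em An \code{ExpressionMatrix} (or bare list with \code{values},
#'   \code{reference_id}, \code{threshold}).
#' @return The matrix with \code{normalized} and \code{calls} repopulated.
#' @export
normalize_and_call <- function(em) {
  expression_matrix(em$values, reference_id = em$reference_id,
                    threshold = em$threshold,
                    gene_category = em$gene_category)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "features x", ncol(x$values),
      "samples; reference", x$reference_id, "; threshold", x$threshold, "\n")
  cat("  expressed per sample:",
      paste(colSums(x$calls), collapse = " "), "\n")
  invisible(x)
}

#' Sharing, union and intersection accounting
#'
#' For each k, the number of genes expressed in at least k and in exactly k
#' of the n samples; k = 1 gives the union, k = n the intersection.
#'
#' @param calls Logical genes-by-samples matrix (or an
#'   \code{ExpressionMatrix}).
#' @return List with \code{per_k} (data.frame k / exactly / at_least),
#'   \code{union}, \code{intersection}, \code{mean_expressed} (average number
#'   of expressed genes per sample).
#' @export
sharing_table <- function(calls) {
  if (inherits(calls, "ExpressionMatrix")) calls <- calls$calls
  n <- ncol(calls)
  if (n < 1) stop("need at least one sample")
  k_per_gene <- rowSums(calls)
  exactly <- vapply(seq_len(n), function(k) sum(k_per_gene == k), numeric(1))
  at_least <- rev(cumsum(rev(exactly)))
  list(per_k = data.frame(k = seq_len(n), exactly = exactly,
                          at_least = at_least),
       union = sum(k_per_gene >= 1),
       intersection = sum(k_per_gene == n),
       mean_expressed = mean(colSums(calls)))
}

#' Expression threshold expressed in PCR doubling cycles
#'
#' A ratio threshold of 1/10,000 relative to the reference corresponds to
#' \code{log2(1/threshold)} doublings (about 13 cycles for the default).
#'
#' @param threshold Expression-ratio cutoff (default \code{1e-4}).
#' @return Number of doubling cycles.
#' @export
threshold_cycles <- function(threshold = 1e-4) log2(1 / threshold)
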