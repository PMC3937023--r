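# Inter-individual Pearson correlation structure, cross-platform Spearman
# correlations, and the within- vs between-group contrast that formalizes
# the pseudogene observation.

#' Pairwise inter-individual Pearson correlations
#'
#' For each pair of samples, the Pearson correlation of
#' \code{log2(normalized + pseudocount)} over the genes of a category,
#' optionally restricted to genes called expressed in both samples of the
#' pair ("shared"); abundances are heavy-tailed, so the log scale keeps the
#' coefficient from being dominated by a handful of extreme transcripts.
#'
#' @param em An \code{ExpressionMatrix}.
#' @param genes Optional character vector restricting to a gene set; if
#'   \code{NULL} and \code{category} is given, rows of that
#'   \code{gene_category} are used; otherwise all rows.
#' @param category Optional category label (e.g. \code{"pseudogene"}) looked
#'   up in \code{em$gene_category}.
#' @param shared_only Restrict each pair to genes expressed in both samples
#'   (default \code{TRUE}).
#' @param log2_transform Correlate on \code{log2(x + pseudocount)} (default)
#'   or on the linear scale.
#' @param pseudocount Added before the log (default \code{1e-6}).
#' @param groups Optional named group label per sample, stored on the result.
#' @return A \code{CorrelationMatrix}: symmetric sample-by-sample matrix with
#'   unit diagonal and attributes \code{groups}, \code{restriction}; pairs
#'   with fewer than 3 usable genes are \code{NA}.
#' @export
pairwise_pearson <- function(em, genes = NULL, category = NULL,
                             shared_only = TRUE, log2_transform = TRUE,
                             pseudocount = 1e-6, groups = NULL) {
  m <- em$normalized
  if (is.null(genes) && !is.null(category)) {
    if (is.null(em$gene_category))
      stop("ExpressionMatrix has no gene_category metadata")
    genes <- rownames(m)[em$gene_category == category]
  }
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  calls <- em$calls[rownames(m), , drop = FALSE]
  ns <- ncol(m)
  if (ns < 2) stop("need at least two samples")
  x <- if (log2_transform) log2(m + pseudocount) else m
  r <- diag(1, ns)
  dimnames(r) <- list(colnames(m), colnames(m))
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      use <- if (shared_only) calls[, i] & calls[, j] else
        rep(TRUE, nrow(m))
      r[i, j] <- r[j, i] <- if (sum(use) < 3) NA_real_ else
        stats::cor(x[use, i], x[use, j])
    }
  }
  structure(r, class = c("CorrelationMatrix", class(r)),
            groups = groups,
            restriction = list(category = category,
                               shared_only = shared_only,
                               log2 = log2_transform,
                               pseudocount = pseudocount))
}

#' Mean off-diagonal correlation
#'
#' @param corr A \code{CorrelationMatrix} (or plain symmetric matrix).
#' @return Mean of the off-diagonal cells, \code{NA}s removed.
#' @export
mean_offdiagonal <- function(corr) {
  m <- unclass(corr)
  mean(m[upper.tri(m)], na.rm = TRUE)
}

#' Intra-individual cross-platform Spearman correlation
#'
#' Per sample, the Spearman rank correlation (midrank ties) between two
#' platforms over the genes present on both, e.g. RNA-seq RPKM against a
#' normalized microarray matrix.  Rank correlation is invariant to the
#' platforms' monotone scale differences.
#'
#' @param rnaseq \code{ExpressionMatrix} (normalized values are used) or a
#'   plain genes-by-samples matrix.
#' @param microarray Same, for the second platform; sample columns must
#'   match by name.
#' @return Named numeric vector: Spearman rho per sample.
#' @export
cross_platform_spearman <- function(rnaseq, microarray) {
  a <- if (inherits(rnaseq, "ExpressionMatrix")) rnaseq$normalized else rnaseq
  b <- if (inherits(microarray, "ExpressionMatrix")) microarray$normalized else
    microarray
  common <- intersect(rownames(a), rownames(b))
  if (!length(common)) stop("no genes shared between the two platforms")
  samples <- intersect(colnames(a), colnames(b))
  if (!length(samples)) stop("no samples shared between the two platforms")
  vapply(samples, function(s) {
    stats::cor(a[common, s], b[common, s], method = "spearman")
  }, numeric(1))
}

#' Within- versus between-group correlation contrast
#'
#' Formalizes the "high within groups, none across groups" pattern: the mean
#' off-diagonal correlation within the two donor groups minus the mean
#' correlation across them, with a label-permutation p-value
#' (\code{(b + 1) / (n + 1)} over permutations whose contrast is at least
#' the observed).
#'
#' @param corr A \code{CorrelationMatrix} (or sample-by-sample matrix).
#' @param labels Group label per sample (named by sample or in column
#'   order); exactly two groups, each with at least two samples.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A \code{GroupContrast}: list with \code{mean_within},
#'   \code{mean_between}, \code{contrast}, \code{p_perm}, \code{n_perm}.
#' @export
group_contrast <- function(corr, labels, n_perm = 10000, seed = NULL) {
  m <- unclass(corr)
  ns <- ncol(m)
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- as.character(labels)
  if (length(labels) != ns) stop("one label per sample required")
  tab <- table(labels)
  if (length(tab) != 2 || any(tab < 2))
    stop("need exactly two groups with >= 2 samples each")
  if (!is.null(seed)) set.seed(seed)
  stat <- function(lab) {
    same <- outer(lab, lab, "==")
    ut <- upper.tri(m)
    mean(m[ut & same], na.rm = TRUE) - mean(m[ut & !same], na.rm = TRUE)
  }
  observed <- stat(labels)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(labels)), numeric(1))
  b <- sum(perm >= observed)
  structure(list(mean_within = mean(m[upper.tri(m) &
                                        outer(labels, labels, "==")],
                                    na.rm = TRUE),
                 mean_between = mean(m[upper.tri(m) &
                                         !outer(labels, labels, "==")],
                                     na.rm = TRUE),
                 contrast = observed,
                 p_perm = (b + 1) / (n_perm + 1),
                 n_perm = n_perm),
            class = "GroupContrast")
}

#' @export
print.GroupContrast <- function(x, ...) {
  cat(sprintf(
    "GroupContrast: within %.3f, between %.3f, contrast %.3f, p_perm %.4g (%d perms)\n",
    x$mean_within, x$mean_between, x$contrast, x$p_perm, x$n_perm))
  invisible(x)
}
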