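# Observed/expected base-coverage enrichment with a shuffled-location null.
#
# The hot loop (>= 1000 reshufflings per category) runs on plain numeric
# vectors: read coverage is reduced once per chromosome to disjoint sorted
# intervals with a cumulative-coverage lookup, so the bases a shuffled
# interval set shares with the reads come from two findInterval calls
# instead of a GRanges overlap per shuffle.

# internal: per-chromosome coverage index of a reduced read set
# C(x) = covered bases in [0, x) for 0-based x
.coverage_index <- function(reads) {
  red <- GenomicRanges::reduce(reads, ignore.strand = TRUE)
  chroms <- unique(as.character(GenomicRanges::seqnames(red)))
  idx <- lapply(chroms, function(chr) {
    r <- red[as.character(GenomicRanges::seqnames(red)) == chr]
    s <- GenomicRanges::start(r) - 1  # 0-based
    e <- GenomicRanges::end(r)
    o <- order(s)
    s <- s[o]; e <- e[o]
    list(s = s, e = e, cum = cumsum(e - s))
  })
  names(idx) <- chroms
  idx
}

# internal: covered bases in [0, x) for vector x, one chromosome index
.cov_at <- function(ci, x) {
  i <- findInterval(x, ci$s)
  out <- numeric(length(x))
  nz <- i > 0
  ii <- i[nz]
  out[nz] <- ci$cum[ii] - pmax(0, ci$e[ii] - x[nz])
  out
}

# internal: bases covered by reads within the union of intervals
# (starts0/ends0 0-based half-open, single chromosome, may overlap)
.union_covered <- function(ci, starts0, ends0) {
  if (is.null(ci) || !length(starts0)) return(0)
  o <- order(starts0)
  s <- starts0[o]; e <- cummax(ends0[o])
  # merge touching/overlapping intervals; e is a running max so each
  # merged run ends at its last element
  keep_start <- c(TRUE, s[-1] > e[-length(e)])
  ms <- s[keep_start]
  me <- e[c(keep_start[-1], TRUE)]
  sum(.cov_at(ci, me) - .cov_at(ci, ms))
}

#' Bases covered by reads inside a category
#'
#' Number of distinct genomic bases lying both under at least one read and
#' inside at least one category interval (strand-blind).
#'
#' @param reads \code{GRanges} of mapped reads.
#' @param intervals \code{GRanges} of category intervals.
#' @return Numeric base count.
#' @export
covered_bases <- function(reads, intervals) {
  if (!length(reads) || !length(intervals)) return(0)
  ci <- .coverage_index(reads)
  df <- .gr0(intervals)
  total <- 0
  for (chr in unique(df$chrom)) {
    if (is.null(ci[[chr]])) next
    sel <- df$chrom == chr
    total <- total + .union_covered(ci[[chr]], df$start[sel], df$end[sel])
  }
  total
}

#' Shuffle the genomic locations of a category
#'
#' Places each interval uniformly at random on its original chromosome with
#' its length preserved; placements are independent, so shuffled intervals
#' may overlap one another.
#'
#' @param intervals \code{GRanges} to relocate.
#' @param genome Named numeric vector of chromosome lengths.
#' @param seed Optional integer seed for reproducibility.
#' @return \code{GRanges} of relocated intervals (strand preserved).
#' @export
shuffle_category <- function(intervals, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- .gr0(intervals)
  w <- df$end - df$start
  len <- genome[df$chrom]
  if (any(is.na(len)))
    stop("interval chromosome absent from genome table")
  if (any(w > len))
    stop("interval longer than its chromosome")
  new_start <- floor(runif(length(w)) * (len - w + 1))
  .gr(df$chrom, new_start, new_start + w, strand = df$strand,
      feature_id = mcols(intervals)$feature_id)
}

#' Permutation feature-enrichment test
#'
#' Enrichment of a category is the ratio of category bases covered by the
#' mapped reads ("observed") over the bases that would have been covered had
#' the category been placed at random ("expected").  The null distribution
#' comes from reshuffling the category locations \code{n_shuffles} times
#' (uniform per-chromosome relocation, lengths preserved); the empirical
#' p-value is \code{(b + 1) / (n + 1)} with \code{b} the number of shuffles
#' at least as extreme as the observation in the direction of the observed
#' deviation.  A category is called significant when the fold change is at
#' least 1.5 in either direction (fold >= 1.5 or <= 1/1.5) and p <= 0.05.
#'
#' @param reads \code{GRanges} of mapped reads.
#' @param category_intervals \code{GRanges} of the category.
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_shuffles Number of reshufflings (>= 1; at least 1000 for
#'   production calls).
#' @param seed Optional integer seed.
#' @param fold_cutoff Fold-change cutoff (default 1.5).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @param alternative Direction of the extreme count: \code{"auto"}
#'   (default; one-sided in the direction of the observed deviation, so
#'   both enrichment and depletion can be called), \code{"enrichment"} or
#'   \code{"depletion"} (fixed one-sided tests, exactly calibrated under
#'   the null).
#' @return An \code{EnrichmentResult}: list with \code{observed_bases},
#'   \code{expected_bases}, \code{fold}, \code{log2_fold}, \code{p_value},
#'   \code{n_shuffles}, \code{significant}.
#' @export
enrichment_test <- function(reads, category_intervals, genome,
                            n_shuffles = 1000, seed = NULL,
                            fold_cutoff = 1.5, p_cutoff = 0.05,
                            alternative = c("auto", "enrichment",
                                            "depletion")) {
  alternative <- match.arg(alternative)
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ci <- .coverage_index(reads)
  df <- .gr0(category_intervals)
  w <- df$end - df$start
  len <- genome[df$chrom]
  if (any(is.na(len))) stop("interval chromosome absent from genome table")
  if (any(w > len)) stop("interval longer than its chromosome")

  observed <- 0
  for (chr in unique(df$chrom)) {
    if (is.null(ci[[chr]])) next
    sel <- df$chrom == chr
    observed <- observed + .union_covered(ci[[chr]], df$start[sel], df$end[sel])
  }

  k <- length(w)
  null_cov <- numeric(n_shuffles)
  chroms <- df$chrom
  max_start <- len - w
  by_chr <- split(seq_len(k), chroms)
  for (j in seq_len(n_shuffles)) {
    s <- floor(runif(k) * (max_start + 1))
    tot <- 0
    for (chr in names(by_chr)) {
      cidx <- ci[[chr]]
      if (is.null(cidx)) next
      ii <- by_chr[[chr]]
      tot <- tot + .union_covered(cidx, s[ii], s[ii] + w[ii])
    }
    null_cov[j] <- tot
  }

  expected <- mean(null_cov)
  if (expected > 0) {
    fold <- observed / expected
  } else {
    fold <- if (observed > 0) Inf else NA_real_
  }
  enriched <- switch(alternative,
                     auto = is.na(fold) || observed >= expected,
                     enrichment = TRUE,
                     depletion = FALSE)
  b <- if (enriched) sum(null_cov >= observed) else sum(null_cov <= observed)
  p <- (b + 1) / (n_shuffles + 1)
  fold_ok <- !is.na(fold) && (fold >= fold_cutoff || fold <= 1 / fold_cutoff)
  significant <- if (is.infinite(fold)) p <= p_cutoff else
    (fold_ok && p <= p_cutoff)
  structure(list(observed_bases = observed, expected_bases = expected,
                 fold = fold, log2_fold = log2(fold), p_value = p,
                 n_shuffles = n_shuffles, significant = significant),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: observed %s, expected %.1f, fold %.3f, p %.4g (%d shuffles)%s\n",
    format(x$observed_bases), x$expected_bases, x$fold, x$p_value,
    x$n_shuffles, if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Enrichment across annotation categories
#'
#' Runs \code{\link{enrichment_test}} for each requested category track of a
#' bundle and tabulates the results.
#'
#' @param reads \code{GRanges} of mapped reads.
#' @param bundle \code{AnnotationBundle}.
#' @param categories Category names; default every non-empty non-derived
#'   track.
#' @param n_shuffles,seed,fold_cutoff,p_cutoff Passed to
#'   \code{\link{enrichment_test}}; per-category seeds are derived from
#'   \code{seed} so results do not depend on category order.
#' @return data.frame: category, observed, expected, fold, log2_fold, p,
#'   significant.
#' @export
enrichment_table <- function(reads, bundle, categories = NULL,
                             n_shuffles = 1000, seed = NULL,
                             fold_cutoff = 1.5, p_cutoff = 0.05) {
  if (is.null(categories)) {
    categories <- setdiff(names(bundle$tracks), feature_categories("derived"))
    categories <- categories[vapply(bundle$tracks[categories], length, 1L) > 0]
  }
  rows <- lapply(seq_along(categories), function(i) {
    cat_ <- categories[i]
    res <- enrichment_test(reads, bundle$tracks[[cat_]], bundle$genome,
                           n_shuffles = n_shuffles,
                           seed = if (is.null(seed)) NULL else seed + i,
                           fold_cutoff = fold_cutoff, p_cutoff = p_cutoff)
    data.frame(category = cat_, observed = res$observed_bases,
               expected = res$expected_bases, fold = res$fold,
               log2_fold = res$log2_fold, p = res$p_value,
               significant = res$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
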