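#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom methods is
#' @importFrom stats setNames rnorm runif
#' @importFrom utils read.delim write.table
NULL

# ---- category vocabulary ----------------------------------------------------

.REPEAT_CLASSES <- c("DNA", "RNA", "LINE", "SINE", "LTR", "RC",
                     "Simple_repeat", "rRNA", "Satellite", "scRNA",
                     "snRNA", "srpRNA", "tRNA", "Other")

.BASE_CATEGORIES <- c("protein_coding_gene_span", "protein_coding_exon",
                      "pseudogene", "lncRNA", .REPEAT_CLASSES)

.DERIVED_CATEGORIES <- c("purely_intronic", "unannotated_intergenic")

#' Feature category vocabulary
#'
#' The closed vocabulary of annotation categories used throughout the
#' package: protein-coding gene spans and exons, pseudogenes, lncRNAs, the
#' 14 RepeatMasker repeat/ncRNA classes, and the two stringently derived
#' tracks (purely intronic, unannotated intergenic).
#'
#' @param which One of \code{"all"}, \code{"base"} (annotated input tracks),
#'   \code{"repeat"} (the 14 RepeatMasker classes) or \code{"derived"}.
#' @return Character vector of category names.
#' @export
#' @examples
#' feature_categories("repeat")
feature_categories <- function(which = c("all", "base", "repeat", "derived")) {
  which <- match.arg(which)
  switch(which,
         all     = c(.BASE_CATEGORIES, .DERIVED_CATEGORIES),
         base    = .BASE_CATEGORIES,
         "repeat" = .REPEAT_CLASSES,
         derived = .DERIVED_CATEGORIES)
}

# ---- AnnotationBundle -------------------------------------------------------

#' Construct an annotation bundle
#'
#' An \code{AnnotationBundle} holds a genome (named vector of chromosome
#' lengths, 0-based half-open coordinates throughout) together with one
#' \code{\link[GenomicRanges]{GRanges}} track per annotation category.  Each
#' track carries a \code{feature_id} metadata column, unique within its
#' category.
#'
#' @param genome Named numeric vector of chromosome lengths in bases.
#' @param tracks Named list of \code{GRanges}; names must come from
#'   \code{\link{feature_categories}()}.
#' @return An object of class \code{AnnotationBundle}.
#' @export
annotation_bundle <- function(genome, tracks = list()) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome must be a named vector of chromosome lengths")
  if (any(genome <= 0)) stop("chromosome lengths must be positive")
  bundle <- structure(list(genome = genome, tracks = tracks),
                      class = "AnnotationBundle")
  validate_bundle(bundle)
  bundle
}

#' Validate an annotation bundle
#'
#' Checks the closed category vocabulary, per-category feature-id uniqueness,
#' and that every interval lies within its chromosome bounds.
#'
#' @param bundle An \code{AnnotationBundle}.
#' @return The bundle, invisibly; errors on violation.
#' @export
validate_bundle <- function(bundle) {
  vocab <- feature_categories("all")
  bad <- setdiff(names(bundle$tracks), vocab)
  if (length(bad))
    stop("unknown annotation categories: ", paste(bad, collapse = ", "))
  for (cat in names(bundle$tracks)) {
    gr <- bundle$tracks[[cat]]
    if (!methods::is(gr, "GRanges"))
      stop("track '", cat, "' is not a GRanges")
    if (length(gr) == 0L) next
    chr <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(chr), names(bundle$genome))
    if (length(unknown))
      stop("track '", cat, "' uses chromosomes absent from the genome table: ",
           paste(unknown, collapse = ", "))
    if (any(GenomicRanges::end(gr) > bundle$genome[chr]))
      stop("track '", cat, "' has intervals beyond chromosome bounds")
    ids <- mcols(gr)$feature_id
    if (!is.null(ids) && anyDuplicated(ids))
      stop("track '", cat, "' has duplicated feature_id values")
  }
  invisible(bundle)
}

#' @export
print.AnnotationBundle <- function(x, ...) {
  cat("AnnotationBundle:", length(x$genome), "chromosome(s),",
      sum(as.numeric(x$genome)), "bases\n")
  for (cat_ in names(x$tracks))
    cat(sprintf("  %-24s %6d features\n", cat_, length(x$tracks[[cat_]])))
  invisible(x)
}

# internal: GRanges from 0-based half-open starts/ends
.gr <- function(chrom, start0, end0, strand = "*", feature_id = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L, end = end0),
                               strand = strand)
  if (!is.null(feature_id)) mcols(gr)$feature_id <- feature_id
  gr
}

# internal: 0-based starts/ends from a GRanges
.gr0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# ---- interval algebra -------------------------------------------------------

#' Subtract one interval set from another
#'
#' Base-level set difference on a single chromosome: returns the maximal
#' disjoint sorted intervals covering exactly the bases of \code{a} not in
#' \code{b}.  Inputs may overlap internally; strand is ignored.
#'
#' @param a,b \code{GRanges} on a single common chromosome (\code{b} may be
#'   empty).
#' @return A reduced, sorted \code{GRanges} on that chromosome.
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20))
#' subtract_intervals(a, b)
subtract_intervals <- function(a, b) {
  chr <- unique(c(as.character(GenomicRanges::seqnames(a)),
                  as.character(GenomicRanges::seqnames(b))))
  if (length(chr) > 1L)
    stop("subtract_intervals: intervals span multiple chromosomes (",
         paste(chr, collapse = ", "), "); malformed input")
  if (length(a) == 0L)
    return(GenomicRanges::GRanges())
  d <- IRanges::setdiff(IRanges::reduce(GenomicRanges::ranges(a)),
                        IRanges::reduce(GenomicRanges::ranges(b)))
  if (!length(d)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chr[1], d)
}

# internal: strand-blind reduced union of a list of GRanges
.pool <- function(grs) {
  grs <- grs[vapply(grs, length, 1L) > 0L]
  if (!length(grs)) return(GenomicRanges::GRanges())
  out <- suppressWarnings(do.call(c, unname(lapply(grs, function(g) {
    GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                           GenomicRanges::ranges(g))
  }))))
  GenomicRanges::reduce(out, ignore.strand = TRUE)
}

#' Derive the purely intronic track
#'
#' The stringent intronic track: for each protein-coding gene, the gene span
#' minus its own exons, then minus every other annotated feature lying
#' \emph{sense} to the pre-mRNA (same strand, or unstranded, which is
#' conservatively treated as sense to both strands).  Antisense features are
#' not subtracted.  Per-gene segments are unioned per strand; because all
#' same-strand exons genome-wide are in the sense pool, a segment overlapping
#' another gene's exon on the same strand is removed automatically.
#'
#' @param bundle An \code{AnnotationBundle} with
#'   \code{protein_coding_gene_span} and \code{protein_coding_exon} tracks;
#'   exons carry a \code{gene_id} metadata column and gene strands must be
#'   \code{+} or \code{-}.
#' @return \code{GRanges} with category metadata \code{purely_intronic} and
#'   generated \code{feature_id}s.
#' @export
derive_purely_intronic <- function(bundle) {
  genes <- bundle$tracks$protein_coding_gene_span
  exons <- bundle$tracks$protein_coding_exon
  if (is.null(genes) || is.null(exons))
    stop("bundle must contain gene spans and exons")
  if (any(as.character(GenomicRanges::strand(genes)) == "*"))
    stop("gene models must be stranded")
  if (is.null(mcols(exons)$gene_id))
    stop("exon track must carry a gene_id column")
  # exons must lie within their gene span (vectorized check)
  gid <- mcols(genes)$feature_id
  ex_gene <- mcols(exons)$gene_id
  m <- match(ex_gene, gid)
  if (anyNA(m))
    stop("exon references unknown gene: ",
         paste(unique(ex_gene[is.na(m)]), collapse = ", "))
  inside <- as.character(GenomicRanges::seqnames(exons)) ==
    as.character(GenomicRanges::seqnames(genes))[m] &
    GenomicRanges::start(exons) >= GenomicRanges::start(genes)[m] &
    GenomicRanges::end(exons) <= GenomicRanges::end(genes)[m]
  if (!all(inside))
    stop("gene ", paste(unique(ex_gene[!inside]), collapse = ", "),
         " has exons outside its span")

  # sense pool per strand: every annotated feature except gene spans,
  # on that strand or unstranded
  feature_tracks <- bundle$tracks[setdiff(names(bundle$tracks),
                                          c("protein_coding_gene_span",
                                            feature_categories("derived")))]
  pool_for <- function(s) {
    .pool(lapply(feature_tracks, function(g) {
      g[as.character(GenomicRanges::strand(g)) %in% c(s, "*")]
    }))
  }

  out <- GenomicRanges::GRanges()
  for (s in c("+", "-")) {
    on_s <- as.character(GenomicRanges::strand(genes)) == s
    gs <- genes[on_s]
    if (!length(gs)) next
    # per-gene span-minus-own-exons in one vectorized psetdiff; the common
    # sense pool can then be subtracted from the union, since
    # (A1 \ P) u (A2 \ P) = (A1 u A2) \ P
    ids <- gid[on_s]
    exg <- exons[ex_gene %in% ids]
    exl <- S4Vectors::split(exg, factor(mcols(exg)$gene_id, levels = ids))
    intr <- unlist(GenomicRanges::psetdiff(gs, exl), use.names = FALSE)
    if (!length(intr)) next
    introns <- GenomicRanges::reduce(
      GenomicRanges::GRanges(GenomicRanges::seqnames(intr),
                             GenomicRanges::ranges(intr)),
      ignore.strand = TRUE)
    pool <- pool_for(s)
    res <- if (length(pool)) {
      suppressWarnings(GenomicRanges::setdiff(introns, pool,
                                              ignore.strand = TRUE))
    } else introns
    if (length(res)) {
      GenomicRanges::strand(res) <- s
      out <- suppressWarnings(c(out, res))
    }
  }
  out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  if (length(out))
    mcols(out)$feature_id <- sprintf("intronic_%05d", seq_along(out))
  mcols(out)$category <- rep("purely_intronic", length(out))
  out
}

#' Derive the unannotated intergenic track
#'
#' Per chromosome, the whole chromosome minus the strand-blind union of every
#' annotated track (protein-coding loci taken as full gene spans, plus all
#' other characterized features).
#'
#' @param bundle An \code{AnnotationBundle} with a populated genome table.
#' @return Unstranded \code{GRanges} with generated \code{feature_id}s.
#' @export
derive_unannotated_intergenic <- function(bundle) {
  base_tracks <- bundle$tracks[setdiff(names(bundle$tracks),
                                       feature_categories("derived"))]
  pool <- .pool(base_tracks)
  out <- GenomicRanges::GRanges()
  for (chr in names(bundle$genome)) {
    whole <- .gr(chr, 0, bundle$genome[[chr]])
    sub <- pool[as.character(GenomicRanges::seqnames(pool)) == chr]
    out <- suppressWarnings(c(out, subtract_intervals(whole, sub)))
  }
  out <- GenomicRanges::sort(out, ignore.strand = TRUE)
  if (length(out))
    mcols(out)$feature_id <- sprintf("intergenic_%05d", seq_along(out))
  mcols(out)$category <- rep("unannotated_intergenic", length(out))
  out
}

#' Attach derived tracks to a bundle
#'
#' Convenience wrapper computing both stringent tracks and storing them in
#' the bundle under their category names.
#'
#' @param bundle An \code{AnnotationBundle}.
#' @return The bundle with \code{purely_intronic} and
#'   \code{unannotated_intergenic} tracks added.
#' @export
add_derived_tracks <- function(bundle) {
  bundle$tracks$purely_intronic <- derive_purely_intronic(bundle)
  bundle$tracks$unannotated_intergenic <- derive_unannotated_intergenic(bundle)
  validate_bundle(bundle)
  bundle
}
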