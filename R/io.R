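# Readers and writers for the plain-text formats the pipeline exchanges.
# Internal coordinates are 0-based half-open; GTF (1-based closed) and BED
# (0-based half-open) are converted at these boundaries only.

#' Read a chromosome-length table
#'
#' Two-column TSV (chromosome, length in bases), no header.
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome_table <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                   stringsAsFactors = FALSE)
  setNames(as.numeric(df$length), df$chrom)
}

#' Write a chromosome-length table
#' @param genome Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @export
write_genome_table <- function(genome, path) {
  write.table(data.frame(names(genome), as.integer(genome)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Uses the \code{gene} and \code{exon} feature rows of a GTF file and the
#' \code{gene_id} attribute to build the \code{protein_coding_gene_span} and
#' \code{protein_coding_exon} tracks.
#'
#' @param path GTF file path.
#' @return List with \code{gene_span} and \code{exon} \code{GRanges}; both
#'   carry \code{feature_id} (and exons \code{gene_id}) metadata.
#' @export
read_gene_models <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  genes <- gtf[gtf$type == "gene"]
  exons <- gtf[gtf$type == "exon"]
  if (!length(genes)) stop("no 'gene' rows in ", path)
  gs <- GenomicRanges::granges(genes)
  mcols(gs)$feature_id <- mcols(genes)$gene_id
  ex <- GenomicRanges::granges(exons)
  mcols(ex)$gene_id <- mcols(exons)$gene_id
  idx <- stats::ave(seq_along(ex), mcols(ex)$gene_id, FUN = seq_along)
  mcols(ex)$feature_id <- sprintf("%s_exon%04d", mcols(ex)$gene_id, idx)
  list(gene_span = gs, exon = ex)
}

#' Read a BED6 feature track
#'
#' @param path BED file path.
#' @param category Optional category label stored on the result.
#' @return \code{GRanges} with \code{feature_id} (BED name column) metadata.
#' @export
read_feature_bed <- function(path, category = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- GenomicRanges::granges(gr)
  mcols(out)$feature_id <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    sprintf("feature_%06d", seq_along(gr))
  if (!is.null(category)) mcols(out)$category <- rep(category, length(out))
  out
}

#' Write a feature track as BED6
#'
#' @param gr \code{GRanges} with a \code{feature_id} metadata column.
#' @param path Output path.
#' @export
write_feature_bed <- function(gr, path) {
  df0 <- .gr0(gr)
  name <- if (!is.null(mcols(gr)$feature_id)) mcols(gr)$feature_id else
    sprintf("feature_%06d", seq_along(gr))
  strand <- ifelse(df0$strand == "*", ".", df0$strand)
  write.table(data.frame(df0$chrom, as.integer(df0$start), as.integer(df0$end),
                         name, 0L, strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read mapped reads from a BED6 file
#'
#' One file per sample; the BED name column is the read id.
#'
#' @param path BED file path.
#' @return \code{GRanges} of reads with \code{read_id} metadata.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- GenomicRanges::granges(gr)
  mcols(out)$read_id <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else
    sprintf("read_%08d", seq_along(gr))
  out
}

#' Write mapped reads as BED6
#' @param reads \code{GRanges} with \code{read_id} metadata.
#' @param path Output path.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- reads
  mcols(gr)$feature_id <- mcols(reads)$read_id
  write_feature_bed(gr, path)
}

#' Read a normalized expression matrix from TSV
#'
#' Genes in rows (first column \code{gene_id}), samples in columns.  Used for
#' the microarray arm, which arrives already normalized.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a gene-by-sample matrix as TSV
#' @param m Matrix with gene-id rownames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quantitative proteome table
#'
#' TSV with columns \code{protein_id}, \code{abundance}, \code{confidence}
#' (percent).
#'
#' @param path TSV path.
#' @return data.frame of proteome entries.
#' @export
read_proteome_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "abundance", "confidence")
  if (!all(need %in% names(df)))
    stop("proteome table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read a gene-to-protein id mapping table
#'
#' TSV with columns \code{gene_id}, \code{protein_id}; may be many-to-one.
#'
#' @param path TSV path.
#' @return data.frame mapping.
#' @export
read_mapping_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "protein_id") %in% names(df)))
    stop("mapping table must have columns gene_id, protein_id")
  df
}
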