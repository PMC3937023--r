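# End-to-end orchestration: simulate -> annotate -> quantify -> enrich ->
# correlate -> compare-proteome, with per-stage outputs and a manifest.

#' Pipeline run configuration
#'
#' Holds the analysis parameters (all defaults are the production values:
#' 16 nt minimum read length, beta-actin reference \code{ENST00000331789},
#' 1e-4 expression-ratio threshold, 1000 reshufflings, +/-1.5 fold and 0.05
#' p-value cutoffs) together with the synthetic cohort configuration and
#' output location.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param threshold Expression-ratio cutoff (default \code{1e-4}).
#' @param reference_id Reference transcript id (default
#'   \code{ENST00000331789}).
#' @param min_read_len Minimum mapped-read length (default 16).
#' @param n_shuffles Reshufflings per enrichment test (default 1000).
#' @param fold_cutoff,p_cutoff Enrichment significance cutoffs (1.5, 0.05).
#' @param n_perm Label permutations for the group contrast (default 10000).
#' @param cohort \code{CohortConfig} for the synthetic arm; its seed is
#'   overridden by \code{seed}.
#' @param proteome \code{ProteomeSimConfig} or \code{NULL} to auto-scale to
#'   the cohort.
#' @return A \code{RunConfig} list.
#' @export
run_config <- function(out_dir, seed = 1, threshold = 1e-4,
                       reference_id = "ENST00000331789", min_read_len = 16,
                       n_shuffles = 1000, fold_cutoff = 1.5, p_cutoff = 0.05,
                       n_perm = 10000, cohort = cohort_config(),
                       proteome = NULL) {
  cohort$seed <- seed
  structure(list(out_dir = out_dir, seed = seed, threshold = threshold,
                 reference_id = reference_id, min_read_len = min_read_len,
                 n_shuffles = n_shuffles, fold_cutoff = fold_cutoff,
                 p_cutoff = p_cutoff, n_perm = n_perm, cohort = cohort,
                 proteome = proteome),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate, annotate, quantify, enrich, correlate and
#' compare-proteome in order, writing every stage's outputs as plain-text
#' TSV/BED under \code{config$out_dir} and finishing with a
#' \code{manifest.json} that echoes the configuration, the seed, the
#' package version and the MD5 checksum of every output file.  A fixed seed
#' gives byte-identical outputs.  Any stage failure aborts with the stage
#' name in the message.
#'
#' @param config A \code{RunConfig}.
#' @return The manifest, invisibly.
#' @export
run_all <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("annotation", "reads", "quantify", "enrich", "correlate",
              "proteome"))
    dir.create(file.path(out, d), showWarnings = FALSE)

  # ---- simulate -------------------------------------------------------------
  sim <- .stage("simulate", {
    bundle <- make_genome(config$cohort)
    read_sets <- simulate_read_sets(bundle, config$cohort)
    write_genome_table(bundle$genome, file.path(out, "annotation",
                                                "genome.tsv"))
    for (cat_ in names(bundle$tracks))
      write_feature_bed(bundle$tracks[[cat_]],
                        file.path(out, "annotation", paste0(cat_, ".bed")))
    for (s in names(read_sets))
      write_reads_bed(read_sets[[s]],
                      file.path(out, "reads", paste0(s, ".bed")))
    list(bundle = bundle, read_sets = read_sets,
         groups = attr(read_sets, "groups"))
  })

  # ---- annotate (derived tracks are part of the bundle; re-validate) --------
  .stage("annotate", validate_bundle(sim$bundle))

  # ---- quantify -------------------------------------------------------------
  qt <- .stage("quantify", {
    bundle <- sim$bundle
    reads <- lapply(sim$read_sets, filter_reads,
                    min_len = config$min_read_len)
    fractions <- lapply(names(reads), function(s) {
      cf <- category_fractions(reads[[s]], bundle)
      cf$sample <- s
      cf
    })
    frac_df <- do.call(rbind, fractions)
    avg <- stats::aggregate(cbind(count, percent) ~ category, frac_df, mean)
    avg <- avg[order(-avg$percent), ]
    write.table(frac_df, file.path(out, "quantify",
                                   "category_breakdown_per_sample.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(avg, file.path(out, "quantify", "category_breakdown.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    exons <- bundle$tracks$protein_coding_exon
    exon_parts <- exons
    mcols(exon_parts)$feature_id <- mcols(exons)$gene_id
    pseudo <- bundle$tracks$pseudogene
    gene_ids <- mcols(bundle$tracks$protein_coding_gene_span)$feature_id
    pseudo_ids <- mcols(pseudo)$feature_id
    lens <- c(feature_lengths(exon_parts), feature_lengths(pseudo))

    rpkm <- sapply(reads, function(r) {
      total <- length(r)
      cts <- c(count_reads_per_feature(r, exon_parts, ids = gene_ids),
               count_reads_per_feature(r, pseudo, ids = pseudo_ids))
      compute_rpkm(cts, lens, total)
    })
    em <- expression_matrix(rpkm, reference_id = config$reference_id,
                            threshold = config$threshold,
                            gene_category = c(rep("mRNA", length(gene_ids)),
                                              rep("pseudogene",
                                                  length(pseudo_ids)))[
                                                    match(rownames(rpkm),
                                                          c(gene_ids,
                                                            pseudo_ids))])
    write_expression_tsv(em$values, file.path(out, "quantify",
                                              "expression_rpkm.tsv"))
    write_expression_tsv(em$normalized,
                         file.path(out, "quantify",
                                   "expression_normalized.tsv"))
    write_expression_tsv(em$calls * 1L,
                         file.path(out, "quantify", "expression_calls.tsv"))
    mrna_calls <- em$calls[em$gene_category == "mRNA", , drop = FALSE]
    sh <- sharing_table(mrna_calls)
    write.table(sh$per_k, file.path(out, "quantify", "sharing.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(reads = reads, em = em, sharing = sh)
  })

  # ---- enrich (pooled reads across donors) ----------------------------------
  enr <- .stage("enrich", {
    pooled <- suppressWarnings(do.call(c, unname(qt$reads)))
    et <- enrichment_table(pooled, sim$bundle,
                           n_shuffles = config$n_shuffles,
                           seed = config$seed + 4L,
                           fold_cutoff = config$fold_cutoff,
                           p_cutoff = config$p_cutoff)
    write.table(et, file.path(out, "enrich", "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    et
  })

  # ---- correlate ------------------------------------------------------------
  corr <- .stage("correlate", {
    groups <- sim$groups
    em <- qt$em
    mrna <- pairwise_pearson(em, category = "mRNA", groups = groups)
    pg <- pairwise_pearson(em, category = "pseudogene", groups = groups)
    ctr <- group_contrast(pg, groups, n_perm = config$n_perm,
                          seed = config$seed + 5L)
    ma <- simulate_microarray(em, seed = config$seed + 2L)
    xp <- cross_platform_spearman(em, ma)
    write_corr <- function(m, path) {
      df <- data.frame(sample = rownames(m), group = groups[rownames(m)],
                       unclass(m), check.names = FALSE)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_corr(mrna, file.path(out, "correlate", "pearson_mrna.tsv"))
    write_corr(pg, file.path(out, "correlate", "pearson_pseudogene.tsv"))
    write.table(data.frame(sample = names(xp), spearman = xp),
                file.path(out, "correlate", "cross_platform_spearman.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(mean_within = ctr$mean_within,
                           mean_between = ctr$mean_between,
                           contrast = ctr$contrast, p_perm = ctr$p_perm,
                           n_perm = ctr$n_perm),
                file.path(out, "correlate", "pseudogene_group_contrast.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(mrna = mrna, pseudogene = pg, contrast = ctr, cross_platform = xp)
  })

  # ---- compare-proteome -----------------------------------------------------
  pc <- .stage("compare-proteome", {
    em <- qt$em
    pcfg <- config$proteome
    if (is.null(pcfg)) pcfg <- scale_proteome_config(em)
    pcfg$seed <- config$seed + 3L
    sim_p <- simulate_proteome(em, pcfg)
    write.table(sim_p$proteome, file.path(out, "proteome", "proteome.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sim_p$mapping, file.path(out, "proteome", "mapping.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cs <- proteome_concordance(sim_p$expression, sim_p$proteome,
                               sim_p$mapping)
    membership <- do.call(rbind, lapply(names(cs$groups), function(g) {
      ids <- cs$groups[[g]]
      if (!length(ids)) return(NULL)
      data.frame(id = ids, group = g, stringsAsFactors = FALSE)
    }))
    write.table(membership, file.path(out, "proteome", "groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(n_pairs = cs$spearman$n, rho = cs$spearman$rho,
                           p = cs$spearman$p),
                file.path(out, "proteome", "concordance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cs
  })

  # ---- manifest -------------------------------------------------------------
  files <- sort(list.files(out, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out, files))
  manifest <- list(
    package = "plateletTx",
    version = as.character(utils::packageVersion("plateletTx")),
    seed = config$seed,
    parameters = list(threshold = config$threshold,
                      reference_id = config$reference_id,
                      min_read_len = config$min_read_len,
                      n_shuffles = config$n_shuffles,
                      fold_cutoff = config$fold_cutoff,
                      p_cutoff = config$p_cutoff,
                      n_perm = config$n_perm),
    cohort = unclass(config$cohort),
    outputs = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, bundle = sim$bundle,
                 expression = qt$em, sharing = qt$sharing,
                 enrichment = enr, correlation = corr, concordance = pc))
}
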