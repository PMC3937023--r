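# plateletTx

Platelets are anucleate blood cells that nevertheless carry a rich
transcriptome inherited from their megakaryocyte precursors. Profiling that
transcriptome across healthy donors raises a set of recurring analysis
questions: what fraction of sequenced reads falls on exons, ribosomal RNA,
repeats, introns or unannotated intergenic space; which genes count as
"expressed" under a stringent reference-anchored threshold; how concordant
are donors with one another (and do donor groups differ for particular
transcript classes, such as pseudogenes); and how well does the mRNA
repertoire agree with the quantitative platelet proteome.

`plateletTx` implements that full analysis as a reusable, tested R package:

* **Annotation hierarchy** — protein-coding gene models, pseudogenes,
  lncRNAs and the 14 RepeatMasker repeat/ncRNA classes over a genome of
  named chromosome lengths, plus two stringently *derived* tracks:
  *purely intronic* regions (intronic sequence left after removing every
  annotated feature lying sense to the pre-mRNA) and *unannotated
  intergenic* regions (the genome minus all protein-coding loci and all
  other characterized features). Interval algebra is built on
  `GenomicRanges`/`IRanges`.
* **Read accounting and expression calls** — uniquely mapped reads shorter
  than 16 nt are discarded; each read is assigned a single category by a
  configurable precedence (exon first, intergenic fallback); gene abundance
  is RPKM

  `RPKM_g = count_g / ( (length_g / 10^3) * (total_mapped / 10^6) )`

  normalized to the β-actin transcript (ENST00000331789), and a gene is
  called expressed in a sample when `RPKM_g / RPKM_ACTB >= 1e-4`
  (1/10,000 of β-actin, about `log2(10^4) ≈ 13` PCR cycles). Sharing
  tables give the union, intersection and per-k sharing counts across
  donors.
* **Feature enrichment** — for each category, the ratio of category bases
  covered by reads ("observed") over the coverage expected when the
  category's locations are reshuffled uniformly per chromosome
  (`>= 1000` reshufflings); empirical p-value `(b+1)/(n+1)`; a category is
  significant at `|fold| >= 1.5` (either direction) and `p <= 0.05`.
* **Correlation structure** — pairwise inter-individual Pearson
  correlations of `log2(normalized + 1e-6)` abundances per transcript
  category (optionally restricted to genes expressed in both donors of a
  pair), intra-individual cross-platform Spearman correlations against a
  microarray matrix, and a within-group vs between-group contrast with a
  label-permutation p-value that formalizes the pseudogene group split.
* **Transcriptome–proteome concordance** — the quantitative proteome is
  filtered to entries with ≥99% confidence, duplicates collapsed to the
  most abundant entry; each protein is paired with its most abundant
  transcript; genes/proteins are partitioned into five non-overlapping
  groups (protein + mRNA in all donors; mRNA in all donors only; protein
  only; mRNA in 1..n−1 donors only; protein + mRNA in 1..n−1 donors); the
  overlap set is scored with a Spearman rank correlation.
* **Synthetic-data generator** — seeded toy genomes, cohort read sets,
  matrix-level expression cohorts, microarray mirrors and quantitative
  proteomes (Gaussian copula with analytically known planted Spearman
  `(6/π)·asin(ρ/2)`), emulating the statistical structure of a ten-donor
  study: ~43% exonic / 36.6% rRNA / 14% intergenic reads, high
  inter-individual mRNA correlation, group-specific pseudogene profiles,
  and reference-scale proteome partition sizes (2,338 / 432 / 3,226 / 774 /
  3,634).

## Worked example

```r
library(plateletTx)

# a seeded ten-donor cohort on a toy annotated genome
cohort <- cohort_config(seed = 1)
bundle <- make_genome(cohort)           # includes derived tracks
reads  <- simulate_read_sets(bundle, cohort)

cf <- category_fractions(filter_reads(reads[[1]]), bundle)
head(cf[order(-cf$percent), ], 5)
#>                category count percent
#>     protein_coding_exon 21495  42.990
#>                    rRNA 18449  36.898
#>  unannotated_intergenic  6853  13.706
#>              pseudogene  1486   2.972
#>                  lncRNA   281   0.562
```

So ~43% of this donor's uniquely mapped reads fall on protein-coding
exons, ~37% on rRNA and ~14% on unannotated intergenic space — the
read-category profile the generator is built to emulate.

```r
# matrix-level cohort at genome scale: proteome comparison and group split
em  <- simulate_expression_cohort(seed = 2)
sim <- simulate_proteome(em, proteome_sim_config(seed = 3))
proteome_concordance(sim$expression, sim$proteome, sim$mapping)
#> ConcordanceSet:
#>   proteome 3544 = 2338 (mRNA all-n) + 774 (mRNA 1..n-1) + 432 (no mRNA)
#>   transcript-side union 9972; no-protein: 3226 (all-n) + 3634 (1..n-1)
#>   overlap Spearman rho = 0.326 (p = 4.5e-59, n = 2338)

pg <- pairwise_pearson(em, category = "pseudogene",
                       groups = attr(em, "groups"))
group_contrast(pg, attr(em, "groups"), n_perm = 10000, seed = 4)
#> GroupContrast: within 0.961, between 0.050, contrast 0.911,
#>                p_perm 0.007699 (10000 perms)
```

The proteome partitions into the five non-overlapping groups (2,338
proteins overlap the all-donor transcriptome, i.e. 87.8% of the 3,544
proteins have a cognate mRNA somewhere), the overlap shows the
characteristic weak rank concordance (ρ ≈ 0.31), and pseudogene profiles
correlate strongly within donor groups (0.96) but not across them (0.05).

A full end-to-end run (`run_all(run_config("out"))`, or
`Rscript inst/scripts/platelet_pipeline.R --out out`) writes BED/TSV
outputs for every stage plus a `manifest.json` with the configuration,
seed and MD5 checksum of every file; a fixed seed gives byte-identical
outputs.

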