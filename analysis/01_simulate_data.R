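#!/usr/bin/env Rscript
# Generate every synthetic input for the downstream analyses:
#  - a 4-condition count matrix (two parents, two reciprocal hybrids,
#    3 replicates) with planted inheritance categories,
#  - alignment records for a co-assembly-sized component set,
#  - per-TE small-RNA read sets for both hybrids with planted ping-pong
#    pairs, plus matched TE expression values anticorrelated with the
#    planted secondary-piRNA signal.
suppressMessages(library(hybridex))

seed <- 20240101
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## expression counts -------------------------------------------------------
design <- sim_design(n_features = 2000, replicates = 3, effect_size = 8,
                     dispersion = 0.05, seed = seed)
sim <- simulate_counts(design)
write_count_table(sim$counts, file.path(out, "counts.tsv"),
                  file.path(out, "design.tsv"))
write.table(sim$truth, file.path(out, "truth_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("counts: %d features x %d samples; planted mix: %s\n",
            nrow(sim$counts$counts), ncol(sim$counts$counts),
            paste(names(table(sim$truth$category)),
                  table(sim$truth$category), collapse = " ", sep = "=")))

## alignment records -------------------------------------------------------
aln <- simulate_alignment_records(21888, seed = seed + 1)
write_alignment_records(aln$records, file.path(out, "alignments.tsv"))
writeLines(aln$components, file.path(out, "components.txt"))
write.table(aln$truth, file.path(out, "truth_alignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("alignments: %d records over %d components\n",
            nrow(aln$records), length(aln$components)))

## small RNAs on TE consensuses -------------------------------------------
# 20 TE families; hybrid A/B ping-pong intensity planted so the secondary
# piRNA ratio anticorrelates with the TE expression ratio between hybrids
set.seed(seed + 2)
n_te <- 20
fams <- sprintf("TEfam%03d", seq_len(n_te))
lfc <- rnorm(n_te, 0, 1.5)                       # log2 expression ratio A/B
# secondary piRNA production tracks -0.8 * lfc with biological noise; the
# primary (background) piRNA pool varies independently of expression, so
# only the secondary-piRNA ratio carries the planted anticorrelation
pairs_a <- pmax(5L, as.integer(round(150 * 2^(-0.8 * lfc + rnorm(n_te, 0, 0.8)))))
pairs_b <- pmax(5L, as.integer(round(150 * 2^rnorm(n_te, 0, 0.8))))
bg_a <- as.integer(round(runif(n_te, 300, 1500)))
bg_b <- as.integer(round(runif(n_te, 300, 1500)))
expr <- data.frame(te = fams,
                   expr_hybridA = round(100 * 2^lfc, 2),
                   expr_hybridB = 100)
write.table(expr, file.path(out, "te_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

consensus_len <- 1200
write_fasta(setNames(vapply(fams, function(f)
  paste(sample(c("A", "C", "G", "T"), consensus_len, TRUE), collapse = ""), ""),
  fams), file.path(out, "te_consensus.fa"))

for (hy in c("A", "B")) {
  reads <- do.call(rbind, lapply(seq_len(n_te), function(i)
    simulate_te_reads(consensus_len,
                      n_pairs = if (hy == "A") pairs_a[i] else pairs_b[i],
                      n_background = if (hy == "A") bg_a[i] else bg_b[i],
                      te_id = fams[i],
                      seed = seed + 10 * i + (hy == "B"))))
  write_smallrna_bed(smallrna_reads(reads),
                     file.path(out, sprintf("pirna_hybrid%s.bed", hy)))
  cat(sprintf("hybrid %s: %d piRNA-sized reads over %d TE families\n",
              hy, nrow(reads), n_te))
}
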