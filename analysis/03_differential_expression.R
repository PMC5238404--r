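#!/usr/bin/env Rscript
# Negative-binomial differential expression for every pairwise contrast the
# inheritance classification needs: parent1 vs parent2, each hybrid vs each
# parent, and hybrid A vs hybrid B. Size factors are shared across
# contrasts; significance = FDR < 0.01 and fold change > 1.5.
suppressMessages(library(hybridex))

out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cm <- read_count_table("results/synthetic/counts.tsv",
                       "results/synthetic/design.tsv")
sf <- size_factors(cm)
cat("size factors:\n"); print(round(sf, 3))

contrasts <- list(p1_p2 = c("parent1", "parent2"),
                  p1_hA = c("parent1", "hybridA"),
                  p2_hA = c("parent2", "hybridA"),
                  p1_hB = c("parent1", "hybridB"),
                  p2_hB = c("parent2", "hybridB"),
                  hA_hB = c("hybridA", "hybridB"))
for (nm in names(contrasts)) {
  res <- de_test(cm, contrasts[[nm]], sf = sf)
  write.table(res, file.path(out, paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-6s %4d significant of %4d tested (%d low-expressed)\n",
              nm, sum(res$significant), sum(!res$low_expressed),
              sum(res$low_expressed)))
}
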