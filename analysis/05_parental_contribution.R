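#!/usr/bin/env Rscript
# Fit the nested linear model of hybrid expression on the mid-parent value
# and the parental half-difference, per hybrid, and test whether the
# half-difference term is needed (a2 = 0 means equal parental contribution).
suppressMessages(library(hybridex))

out <- "results/parental"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
de <- function(nm) read.delim(file.path("results/de", paste0("de_", nm, ".tsv")))

p12 <- de("p1_p2")
keep <- !p12$low_expressed
rows <- NULL
for (hy in c("A", "B")) {
  dh <- de(paste0("p1_h", hy))
  fit <- fit_parental(dh$mean_b[keep], dh$mean_a[keep], p12$mean_b[keep])
  cat(sprintf("hybrid %s:\n", hy)); print(fit)
  rows <- rbind(rows, data.frame(hybrid = hy, a1 = fit$a1, a2 = fit$a2,
                                 r2_full = fit$r2_full,
                                 r2_reduced = fit$r2_reduced,
                                 f_stat = fit$f_stat, p_value = fit$p_value,
                                 n = fit$n))
}
write.table(rows, file.path(out, "parental_fits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
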