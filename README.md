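# hybridex

Analysis toolkit for reciprocal-hybrid transcriptomes: when two closely
related *Drosophila* species are crossed in both directions, how is gene and
transposable-element (TE) expression inherited in the F1 ovary, and do piRNA
defenses keep TEs silenced? `hybridex` implements the full computational
chain for that question on bulk RNA-seq counts and mapped small-RNA reads:

* **Component annotation** of a de novo co-assembled transcriptome against a
  gene set, genome and TE database with identity/coverage rules (genes and
  genome: ≥ 80% identity, ≥ 80% coverage; TEs: > 70% identity, ≥ 80%
  coverage), clustering into gene/TE-family features, and assembly QC
  (chimera-candidate fraction, cross-assembly association).
* **Negative-binomial differential expression**: median-of-ratios size
  factors, per-feature method-of-moments dispersion, NB-GLM Wald test,
  Benjamini–Hochberg correction, and the joint call
  *significant ⇔ FDR < 0.01 and fold change > 1.5*, with a low-expression
  filter (normalized mean ≤ 5 in every condition).
* **Expression-inheritance classification** of every feature into
  conserved, additive, parent-dominant, over-dominant or under-dominant
  from the three pairwise comparisons (P1–P2, H–P1, H–P2).
* **Parental-contribution model**: nested OLS of hybrid expression
  `Hyb ~ a1·(P1+P2)/2 + a2·(P1−P2)/2` with an F-test of `a2 = 0`
  (equal parental contribution).
* **piRNA ping-pong detection**: 5′ overlap histograms (1–26 nt) of
  sense/antisense read pairs on TE consensuses, the 10-nt signature
  (`z10`, `fraction10`), secondary-piRNA counts and strand-resolved
  coverage.
* **Correlation reports** (Pearson r, Fisher-z 95% CI, t-test) linking
  between-hybrid TE expression ratios to piRNA ratios.

A synthetic-data generator plants known inheritance categories, ping-pong
pairs and annotation categories, so the entire pipeline is testable without
any sequencing data. See the methods vignette
(`vignettes/hybrid-transcriptome-methods.Rmd`) for the models, defaults and
their rationale.

## Worked example

The `analysis/` scripts run the whole workflow on synthetic data
(`Rscript analysis/01_simulate_data.R` … `07_te_pirna_correlation.R`,
outputs under `results/`). The core steps in code, on a 2,000-feature
simulated design (4 conditions × 3 replicates, effect size 8, NB dispersion
0.05):

```r
library(hybridex)

design <- sim_design(n_features = 2000, effect_size = 8,
                     dispersion = 0.05, seed = 20240101)
sim <- simulate_counts(design)
cm  <- sim$counts
sf  <- size_factors(cm)

de12 <- de_test(cm, c("parent1", "parent2"), sf = sf)
sum(de12$significant)
#> [1] 406

calls <- classify_inheritance(de12,
                              de_test(cm, c("parent1", "hybridA"), sf = sf),
                              de_test(cm, c("parent2", "hybridA"), sf = sf))
table(calls$category)
#>
#>       additive      ambiguous      conserved low_expression    over_dominant
#>             94             63           1370              6            100
#>    p1_dominant    p2_dominant under_dominant
#>            137            145             85
```

406 of 1,994 tested features differ between the parents (the planted
non-conserved fraction is 30%, but only features clearing both the FDR and
the 1.5-fold criterion are called). The inheritance spectrum recovers the
planted mix (70% conserved, 10% additive, 5% each dominant/over/under;
91% of tested features receive their planted category).

```r
deh <- de_test(cm, c("parent1", "hybridA"), sf = sf)
keep <- !de12$low_expressed
fit_parental(deh$mean_b[keep], deh$mean_a[keep], de12$mean_b[keep])
#> Parental-contribution model (hybrid ~ mid-parent + half-difference)
#>   n features : 1994  (log2(x+1) scale)
#>   a1 (mid-parent)      : 0.9942
#>   a2 (half-difference) : -0.0233
#>   R2 full / reduced    : 0.8780 / 0.8779
#>   F-test a2 = 0        : F = 0.410, p = 0.522
```

The mid-parent value explains hybrid expression (`a1 ≈ 1`) and the
parental-difference term adds nothing (`a2 ≈ 0`, p = 0.52) — as expected,
since the generator plants no parental effect.

```r
reads <- simulate_te_reads(1000, n_pairs = 500, n_background = 100, seed = 5)
pingpong_signature(overlap_histogram(reads, "TE1"))[c("argmax", "z10", "fraction10")]
#> $argmax
#> [1] 10
#>
#> $z10
#> [1] 34.27587
#>
#> $fraction10
#> [1] 0.09691272
```

The planted ping-pong pairs produce the diagnostic peak at a 10-nt 5′
overlap, 34 standard deviations above the off-peak background.

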