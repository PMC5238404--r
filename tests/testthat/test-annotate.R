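rec <- function(q, t, cls, id, cov)
  data.frame(query = q, target = t, target_class = cls,
             identity = id, coverage = cov, stringsAsFactors = FALSE)

test_that("component classification follows the identity/coverage rules", {
  expect_equal(classify_components(rec("c1", "geneA", "gene_set", 95, 90))$category,
               "unique_gene")
  # two qualifying hits to distinct genes
  two <- rbind(rec("c1", "geneX", "gene_set", 85, 85),
               rec("c1", "geneY", "gene_set", 81, 92))
  expect_equal(classify_components(two)$category, "multi_gene")
  # two hits to the SAME gene are still unique_gene
  same <- rbind(rec("c1", "geneX", "gene_set", 85, 85),
                rec("c1", "geneX", "gene_set", 92, 95))
  ann <- classify_components(same)
  expect_equal(ann$category, "unique_gene")
  expect_equal(ann$target, "geneX")
  # genome-only hit
  expect_equal(classify_components(rec("c1", "chr1", "genome", 90, 90))$category,
               "intergenic")
  # nothing qualifying
  expect_equal(classify_components(rec("c1", "chr1", "genome", 60, 90))$category,
               "unmapped")
  # a component with no record at all is unmapped
  ann <- classify_components(rec("c1", "geneA", "gene_set", 95, 90),
                             components = c("c1", "c2"))
  expect_equal(ann$category[ann$component == "c2"], "unmapped")
})

test_that("gene thresholds are inclusive but the TE identity bound is strict", {
  expect_equal(classify_components(rec("c", "g", "gene_set", 80.0, 80.0))$category,
               "unique_gene")
  expect_equal(classify_components(rec("c", "g", "gene_set", 79.9, 80))$category,
               "unmapped")
  expect_equal(classify_components(rec("c", "f", "te_db", 70.0, 95))$category,
               "unmapped")
  expect_equal(classify_components(rec("c", "f", "te_db", 70.1, 95))$category,
               "te")
  expect_equal(classify_components(rec("c", "f", "te_db", 75, 80.0))$category,
               "te")
})

test_that("precedence is gene over TE over intergenic, with best-identity TE family", {
  multi <- rbind(rec("c", "geneA", "gene_set", 90, 90),
                 rec("c", "famZ", "te_db", 95, 95),
                 rec("c", "chr1", "genome", 95, 95))
  expect_equal(classify_components(multi)$category, "unique_gene")
  te_gen <- rbind(rec("c", "famB", "te_db", 88, 95),
                  rec("c", "famA", "te_db", 92, 95),
                  rec("c", "chr1", "genome", 95, 95))
  ann <- classify_components(te_gen)
  expect_equal(ann$category, "te")
  expect_equal(ann$target, "famA")          # highest identity wins
  tie <- rbind(rec("c", "famB", "te_db", 92, 95),
               rec("c", "famA", "te_db", 92, 95))
  expect_equal(classify_components(tie)$target, "famA")  # lexicographic tie-break
})

test_that("categories partition the component set on random inputs", {
  for (s in 1:3) {
    sim <- simulate_alignment_records(300, seed = s)
    ann <- classify_components(sim$records, components = sim$components)
    expect_equal(nrow(ann), 300)
    expect_equal(anyDuplicated(ann$component), 0L)
    expect_equal(sum(table(ann$category)), 300)
    # planted mix recovered exactly: categories are deterministic given records
    expect_equal(table(ann$category)[names(table(sim$truth$category))],
                 table(sim$truth$category))
  }
})

test_that("raising thresholds never gains gene assignments (monotonicity)", {
  sim <- simulate_alignment_records(300, seed = 11)
  n_gene <- function(id_t, cov_t) {
    a <- classify_components(sim$records, components = sim$components,
                             gene_id_thresh = id_t, gene_cov_thresh = cov_t)
    sum(a$category %in% c("unique_gene", "multi_gene"))
  }
  base <- n_gene(80, 80)
  expect_lte(n_gene(90, 80), base)
  expect_lte(n_gene(80, 90), base)
  expect_lte(n_gene(95, 95), n_gene(90, 90))
})

test_that("clustering sums member components and conserves sample totals", {
  mat <- matrix(c(5, 7, 8, 2, 1, 3), nrow = 3,
                dimnames = list(c("c1", "c2", "c3"), c("s1", "s2")))
  cm <- count_matrix(mat, c(s1 = "a", s2 = "b"))
  ann <- data.frame(component = c("c1", "c2", "c3"),
                    category = "unique_gene", target = "geneA",
                    stringsAsFactors = FALSE)
  fc <- cluster_to_features(ann, cm)
  expect_equal(unname(fc$counts["geneA", "s1"]), 20L)   # 5 + 7 + 8
  expect_equal(unname(fc$counts["geneA", "s2"]), 6L)

  sim <- simulate_alignment_records(250, seed = 6,
                                    category_mix = c(unique_gene = 0.4,
                                                     multi_gene = 0.1,
                                                     intergenic = 0.3,
                                                     te = 0.15, unmapped = 0.05))
  ann <- classify_components(sim$records, components = sim$components)
  cmat <- matrix(rpois(250 * 4, 30), nrow = 250,
                 dimnames = list(sim$components, paste0("s", 1:4)))
  cm <- count_matrix(cmat, setNames(c("a", "a", "b", "b"), paste0("s", 1:4)))
  fc <- cluster_to_features(ann, cm)
  expect_equal(colSums(fc$counts), colSums(cm$counts))  # conservation
  # singleton categories keep their component id as feature id
  inter <- ann$component[ann$category == "intergenic"]
  expect_true(all(inter %in% rownames(fc$counts)))
  expect_error(cluster_to_features(ann[-1, ], cm), "without annotation")
})

test_that("TE components cluster into their planted families", {
  # a TE-rich record set: every planted family should come out as one feature
  sim <- simulate_alignment_records(219, category_mix = c(te = 1),
                                    n_te_families = 69, seed = 10)
  ann <- classify_components(sim$records, components = sim$components)
  expect_equal(sort(unique(ann$target)), sort(unique(sim$truth$te_family)))
  cmat <- matrix(rpois(219 * 2, 10), nrow = 219,
                 dimnames = list(sim$components, c("s1", "s2")))
  cm <- count_matrix(cmat, c(s1 = "a", s2 = "b"))
  fc <- cluster_to_features(ann, cm)
  expect_equal(nrow(fc$counts), length(unique(sim$truth$te_family)))
})

test_that("chimera fraction is the unmapped share of components", {
  ann <- data.frame(component = paste0("c", 1:4),
                    category = c("unique_gene", "unmapped", "te", "unmapped"))
  expect_equal(chimera_fraction(ann), 0.5)
  allm <- data.frame(component = "c1", category = "unique_gene")
  expect_equal(chimera_fraction(allm), 0)
  expect_error(chimera_fraction(ann[0, ]), "empty")
  for (s in 1:3) {
    sim <- simulate_alignment_records(200, seed = s)
    ann <- classify_components(sim$records, components = sim$components)
    expect_equal(chimera_fraction(ann),
                 sum(sim$truth$category == "unmapped") / 200)
  }
})

test_that("assembly association counts match brute-force set cardinality", {
  coasm <- paste0("co", 1:50)
  none <- associate_assemblies(rec("q", "x", "genome", 50, 50), coasm)
  expect_equal(none$n_associated, 0)
  expect_equal(none$n_lost, 50)
  all_hit <- rec(paste0("q", 1:50), coasm, "genome", 99, 99)
  expect_equal(associate_assemblies(all_hit, coasm)$n_lost, 0)
  set.seed(2)
  for (i in 1:3) {
    hits <- rec(sprintf("q%d", 1:80),
                sample(coasm, 80, replace = TRUE), "genome",
                runif(80, 50, 100), runif(80, 50, 100))
    got <- associate_assemblies(hits, coasm)
    manual <- length(unique(hits$target[hits$identity >= 80 &
                                        hits$coverage >= 80]))
    expect_equal(got$n_associated, manual)
    expect_equal(got$n_lost, 50 - manual)
  }
})
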