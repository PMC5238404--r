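test_that("size factors are median-of-ratios with the expected identities", {
  # two identical samples
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # hand-computed: every feature's ratios are 1/sqrt(2) and sqrt(2)
  m2 <- matrix(c(100, 50, 10, 200, 100, 20), ncol = 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  # scale equivariance: multiplying one sample by c multiplies its factor
  # relative to the others by c (the geometric-mean reference shifts too,
  # so equivariance holds for factor ratios)
  m3 <- m2; m3[, 2] <- m3[, 2] * 3
  r2 <- size_factors(m2)
  r3 <- size_factors(m3)
  expect_equal(r3[["s2"]] / r3[["s1"]], 3 * r2[["s2"]] / r2[["s1"]])
  # all features hit a zero somewhere -> geometric means all zero -> fatal
  z <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(z), "size factors undefined")
})

test_that("low-expression filter requires all condition means at or below threshold", {
  norm <- rbind(f1 = c(4, 4, 3, 3, 5, 5, 2, 2),
                f2 = c(4, 4, 3, 3, 6, 6, 2, 2))
  cond <- rep(c("p1", "p2", "hA", "hB"), each = 2)
  flags <- low_expression_filter(norm, cond)
  expect_true(flags[["f1"]])     # condition means 4,3,5,2 all <= 5
  expect_false(flags[["f2"]])    # one condition mean is 6
  # brute-force oracle on a matrix spanning the boundary
  set.seed(3)
  nm <- matrix(runif(200 * 8, 0, 12), nrow = 200,
               dimnames = list(sprintf("g%03d", 1:200), NULL))
  got <- low_expression_filter(nm, cond, threshold = 5)
  want <- apply(nm, 1, function(row)
    all(vapply(unique(cond), function(cc) mean(row[cond == cc]) <= 5, TRUE)))
  expect_equal(unname(got), unname(want))
})

test_that("method-of-moments dispersion recovers the generating parameter", {
  cond <- rep(c("A", "B"), each = 200)
  set.seed(1)
  # Poisson data: variance = mean, so alpha collapses to the floor
  pois <- matrix(rpois(50 * 400, 100), nrow = 50)
  a_pois <- estimate_dispersion(pois, cond, c("A", "B"))
  expect_lt(mean(a_pois), 0.005)
  # constant counts: zero variance -> floor exactly
  const <- matrix(7, nrow = 3, ncol = 400)
  expect_equal(unname(estimate_dispersion(const, cond, c("A", "B"))),
               rep(1e-8, 3))
  # NB with alpha = 0.1 at n = 200 per condition
  nb <- matrix(rnbinom(100 * 400, mu = 150, size = 10), nrow = 100)
  a_nb <- estimate_dispersion(nb, cond, c("A", "B"))
  expect_lt(abs(mean(a_nb) - 0.1) / 0.1, 0.2)
})

test_that("NB Wald test handles identity and degenerate features", {
  mat <- rbind(same = c(30L, 40L, 50L, 30L, 40L, 50L),
               zero = c(0L, 0L, 0L, 0L, 0L, 0L),
               up = c(20L, 25L, 22L, 220L, 250L, 210L))
  colnames(mat) <- paste0("s", 1:6)
  cm <- count_matrix(mat, setNames(rep(c("A", "B"), each = 3), colnames(mat)))
  sf1 <- setNames(rep(1, 6), colnames(mat))  # equal depths by construction
  res <- call_significant(nb_test(cm, c("A", "B"), sf = sf1,
                                  low_expressed = rep(FALSE, 3)))
  same <- res[res$feature == "same", ]
  expect_equal(same$log2fc, 0)
  expect_false(same$significant)
  zero <- res[res$feature == "zero", ]
  expect_equal(zero$pvalue, 1)
  expect_equal(zero$fold_change, 1)
  up <- res[res$feature == "up", ]
  expect_true(up$significant)
  expect_gt(up$log2fc, 3)
  expect_error(nb_test(cm, c("A", "missing")), "absent")
})

test_that("Wald p agrees with a brute-force NB likelihood-ratio oracle", {
  set.seed(7)
  alpha <- 0.05
  cases <- list(c(180L, 210L, 160L, 95L, 120L, 80L),
                c(40L, 55L, 45L, 90L, 120L, 100L),
                c(300L, 260L, 340L, 150L, 180L, 140L))
  for (y in cases) {
    mat <- matrix(y, nrow = 1, dimnames = list("f", paste0("s", 1:6)))
    cm <- count_matrix(mat, setNames(rep(c("A", "B"), each = 3),
                                     colnames(mat)))
    res <- nb_test(cm, c("A", "B"), sf = setNames(rep(1, 6), colnames(mat)),
                   dispersions = alpha, low_expressed = FALSE)
    p_lrt <- brute_nb_lrt(y[1:3], y[4:6], alpha)
    expect_lt(res$pvalue / p_lrt, 2)
    expect_gt(res$pvalue / p_lrt, 0.5)
  }
})

test_that("the joint significance rule needs both FDR and fold-change", {
  res <- data.frame(feature = paste0("f", 1:5),
                    fold_change = c(1.4, 2.0, 2.0, 1.5, 4.0),
                    fdr = c(0.005, 0.005, 0.01, 0.001, NA),
                    low_expressed = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- call_significant(res)
  expect_equal(out$significant,
               c(FALSE,   # fold change below 1.5: the ratio half fails
                 TRUE,    # both strict criteria hold
                 FALSE,   # fdr exactly at 0.01 is not below it
                 FALSE,   # fold change exactly 1.5 is not above it
                 FALSE))  # low expressed features are never called
})

test_that("results are invariant to depth scaling and replicate order", {
  d <- sim_design(n_features = 80, seed = 21)
  cm <- simulate_counts(d)$counts
  res <- de_test(cm, c("parent1", "parent2"))
  # scaling one sample's counts is absorbed by the size factors up to a
  # global rescale of the normalized axis: the ratio of normalized means to
  # the original run is one constant across all features
  sc <- cm$counts
  sc[, 1] <- sc[, 1] * 3L
  res_sc <- de_test(count_matrix(sc, setNames(cm$condition, colnames(sc))),
                    c("parent1", "parent2"))
  rescale <- res_sc$mean_a / res$mean_a
  expect_lt(diff(range(rescale)), 1e-9)
  expect_equal(res_sc$mean_b / res$mean_b, rescale, tolerance = 1e-9)
  # doubling every count everywhere leaves size factors fixed and the
  # normalized scale doubled; fold changes move only through the 0.5
  # pseudocount, i.e. negligibly for expressed features, and planted calls
  # are unchanged
  cm2 <- count_matrix(cm$counts * 2L, setNames(cm$condition, colnames(cm$counts)))
  res2 <- de_test(cm2, c("parent1", "parent2"))
  expressed <- pmax(res$mean_a, res$mean_b) > 5
  expect_equal(res2$fold_change[expressed], res$fold_change[expressed],
               tolerance = 0.02)
  expect_equal(res2$significant[expressed], res$significant[expressed])
  # permuting replicates within a condition changes nothing
  perm <- c(3, 1, 2, 4:12)
  cm3 <- count_matrix(cm$counts[, perm],
                      setNames(cm$condition[perm], colnames(cm$counts)[perm]))
  res3 <- de_test(cm3, c("parent1", "parent2"))
  expect_equal(res3$pvalue, res$pvalue, tolerance = 1e-9)
  # BH output is monotone in raw p and bounded
  tested <- res[!res$low_expressed, ]
  ord <- order(tested$pvalue)
  expect_true(all(diff(tested$fdr[ord]) >= -1e-12))
  expect_true(all(tested$fdr >= 0 & tested$fdr <= 1))
})

test_that("size factors agree with the DESeq2 estimator on positive matrices", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  # odd feature count and no zeros: the two median conventions coincide
  mat <- matrix(rpois(101 * 6, 200) + 1L, nrow = 101,
                dimnames = list(sprintf("g%03d", 1:101), paste0("s", 1:6)))
  expect_equal(unname(size_factors(mat)),
               unname(DESeq2::estimateSizeFactorsForMatrix(mat)),
               tolerance = 1e-8)
})
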