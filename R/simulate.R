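#' Simulation design for a reciprocal-hybrid expression experiment
#'
#' Describes a four-condition experiment (two parental lines, two reciprocal
#' hybrids) with planted expression-inheritance categories. The generator
#' draws negative-binomial counts around planted per-condition means, so the
#' full downstream pipeline (normalization, NB testing, inheritance
#' classification) can be validated against known truth.
#'
#' @param n_features number of features (genes/TEs) to simulate.
#' @param replicates replicates per condition; at least 2 (differential
#'   expression testing needs replication).
#' @param category_mix named proportions over the six inheritance categories
#'   (`conserved`, `additive`, `p1_dominant`, `p2_dominant`, `over_dominant`,
#'   `under_dominant`); must sum to 1.
#' @param effect_size fold-change multiplier (> 1) separating parental means
#'   in non-conserved categories and scaling over/under-dominant hybrids.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2);
#'   either a single value or one per feature. 0 gives Poisson counts.
#' @param libsize_factors positive per-sample library-size multipliers, one
#'   per sample (4 * replicates), or NULL for all 1.
#' @param mean_range range of baseline feature means; drawn log-uniformly so
#'   features span the low-expression filter boundary.
#' @param seed integer seed.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_features = 2000,
                       replicates = 3,
                       category_mix = c(conserved = 0.70, additive = 0.10,
                                        p1_dominant = 0.05, p2_dominant = 0.05,
                                        over_dominant = 0.05, under_dominant = 0.05),
                       effect_size = 8,
                       dispersion = 0.05,
                       libsize_factors = NULL,
                       mean_range = c(5, 5000),
                       seed = 1L) {
  if (n_features < 1) stop("n_features must be positive")
  if (replicates < 2) stop("replicates_per_condition must be >= 2: DE testing needs replication")
  cats <- c("conserved", "additive", "p1_dominant", "p2_dominant",
            "over_dominant", "under_dominant")
  if (is.null(names(category_mix)) || !all(names(category_mix) %in% cats))
    stop("category_mix must be named with inheritance categories: ",
         paste(cats, collapse = ", "))
  mix <- setNames(numeric(length(cats)), cats)
  mix[names(category_mix)] <- category_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("category_mix proportions must sum to 1")
  if (any(mix < 0)) stop("category_mix proportions must be non-negative")
  if (effect_size <= 1) stop("effect_size must be > 1")
  n_samples <- 4L * replicates
  if (is.null(libsize_factors)) libsize_factors <- rep(1, n_samples)
  if (length(libsize_factors) != n_samples)
    stop("libsize_factors must have one entry per sample (", n_samples, ")")
  if (any(libsize_factors <= 0)) stop("libsize_factors must all be > 0")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (!length(dispersion) %in% c(1L, n_features))
    stop("dispersion must be scalar or one value per feature")
  structure(list(n_features = as.integer(n_features),
                 conditions = c("parent1", "parent2", "hybridA", "hybridB"),
                 replicates = as.integer(replicates),
                 category_mix = mix,
                 effect_size = effect_size,
                 dispersion = dispersion,
                 libsize_factors = libsize_factors,
                 mean_range = mean_range,
                 seed = as.integer(seed)),
            class = "sim_design")
}

# Deterministic category counts from proportions (largest-remainder partition),
# so a planted mix of 0.7/0.1/... lands on exact feature counts.
.category_counts <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a count matrix with planted inheritance categories
#'
#' Draws NB(mean = planted mean x library-size factor, dispersion) counts for
#' every feature and sample. Planted hybrid means follow the category
#' definitions: conserved features share one mean across all conditions;
#' additive hybrids sit at the mid-parent value; parent-dominant hybrids copy
#' that parent's mean; over-dominant hybrids are `effect_size` times the
#' higher parental mean and under-dominant hybrids the lower parental mean
#' divided by `effect_size`. Both reciprocal hybrids receive the same planted
#' mean (parental effects are not planted).
#'
#' @param design a [sim_design()] object.
#' @return a list with `counts` (a [count_matrix()]) and `truth`, a
#'   data.frame of the planted category and per-condition means per feature
#'   (every simulated feature appears exactly once).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n <- design$n_features
  reps <- design$replicates
  eff <- design$effect_size

  counts_per_cat <- .category_counts(design$category_mix, n)
  category <- sample(rep(names(design$category_mix), counts_per_cat))

  base <- exp(runif(n, log(design$mean_range[1]), log(design$mean_range[2])))
  # Parental means: non-conserved categories separate the parents by the
  # effect size, direction chosen at random per feature.
  up <- runif(n) < 0.5
  mean_p1 <- base
  mean_p2 <- base
  parents_differ <- category %in% c("additive", "p1_dominant", "p2_dominant")
  mean_p2[parents_differ] <- ifelse(up[parents_differ],
                                    base[parents_differ] * eff,
                                    base[parents_differ] / eff)
  mean_h <- base
  mean_h[category == "additive"] <- (mean_p1[category == "additive"] +
                                     mean_p2[category == "additive"]) / 2
  mean_h[category == "p1_dominant"] <- mean_p1[category == "p1_dominant"]
  mean_h[category == "p2_dominant"] <- mean_p2[category == "p2_dominant"]
  mean_h[category == "over_dominant"] <-
    eff * pmax(mean_p1, mean_p2)[category == "over_dominant"]
  mean_h[category == "under_dominant"] <-
    pmin(mean_p1, mean_p2)[category == "under_dominant"] / eff

  feature <- sprintf("feat%05d", seq_len(n))
  condition <- rep(design$conditions, each = reps)
  sample_id <- paste(condition, rep(seq_len(reps), times = 4), sep = "_r")
  mu_cond <- cbind(parent1 = mean_p1, parent2 = mean_p2,
                   hybridA = mean_h, hybridB = mean_h)
  alpha <- rep(design$dispersion, length.out = n)

  mat <- matrix(0L, nrow = n, ncol = length(sample_id),
                dimnames = list(feature, sample_id))
  for (j in seq_along(sample_id)) {
    mu <- mu_cond[, condition[j]] * design$libsize_factors[j]
    y <- ifelse(alpha > 0,
                stats::rnbinom(n, mu = mu, size = 1 / alpha),
                stats::rpois(n, lambda = mu))
    mat[, j] <- as.integer(y)
  }

  truth <- data.frame(feature = feature, category = category,
                      mean_p1 = mean_p1, mean_p2 = mean_p2,
                      mean_hybrid = mean_h, stringsAsFactors = FALSE)
  list(counts = count_matrix(mat, setNames(condition, sample_id)),
       truth = truth)
}

#' Simulate small-RNA reads on a TE consensus with planted ping-pong pairs
#'
#' Emits `n_pairs` sense/antisense read pairs whose 5' ends overlap by
#' exactly 10 nt on opposite strands -- the ping-pong signature -- plus
#' `n_background` reads at uniform random positions and strands (50/50).
#' Read lengths are uniform over `read_lengths`. Reads that would extend
#' past the consensus have their positions resampled.
#'
#' @param consensus_length length of the TE consensus in nt (> 60).
#' @param n_pairs number of planted ping-pong pairs.
#' @param n_background number of background reads.
#' @param read_lengths candidate read lengths (piRNA-sized by default).
#' @param te_id consensus identifier for the emitted reads.
#' @param seed integer seed.
#' @return a `smallrna_reads` data.frame (see [smallrna_reads()]).
#' @export
simulate_te_reads <- function(consensus_length, n_pairs, n_background,
                              read_lengths = 23:29, te_id = "TE1", seed = 1L) {
  if (consensus_length <= 60) stop("consensus_length must be > 60")
  set.seed(seed)
  recs <- list()
  if (n_pairs > 0) {
    lp <- sample(read_lengths, n_pairs, replace = TRUE)
    lm_ <- sample(read_lengths, n_pairs, replace = TRUE)
    # plus 5' at p (0-based start); minus 5' end at p + 9 so the two 5' ends
    # overlap by exactly 10 nt. Constrain so both reads fit the consensus.
    lo <- pmax(0L, lm_ - 10L)
    hi <- consensus_length - pmax(lp, 10L)
    if (any(hi < lo)) stop("consensus too short for requested read lengths")
    p <- lo + floor(runif(n_pairs) * (hi - lo + 1))
    recs$pair_plus <- data.frame(consensus = te_id, start = p, end = p + lp,
                                 read_id = sprintf("pp%d_s", seq_len(n_pairs)),
                                 length = lp, strand = "+",
                                 stringsAsFactors = FALSE)
    m5 <- p + 9L
    recs$pair_minus <- data.frame(consensus = te_id, start = m5 - lm_ + 1L,
                                  end = m5 + 1L,
                                  read_id = sprintf("pp%d_a", seq_len(n_pairs)),
                                  length = lm_, strand = "-",
                                  stringsAsFactors = FALSE)
  }
  if (n_background > 0) {
    lb <- sample(read_lengths, n_background, replace = TRUE)
    st <- floor(runif(n_background) * (consensus_length - lb + 1))
    recs$background <- data.frame(consensus = te_id, start = st, end = st + lb,
                                  read_id = sprintf("bg%d", seq_len(n_background)),
                                  length = lb,
                                  strand = sample(c("+", "-"), n_background,
                                                  replace = TRUE),
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- data.frame(consensus = character(), start = integer(),
                                      end = integer(), read_id = character(),
                                      length = integer(), strand = character(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  smallrna_reads(out)
}

#' Simulate component alignment records with planted annotation categories
#'
#' Generates PSL-like alignment records (query, target, target class, percent
#' identity, query coverage) for `n_components` assembled components so that
#' each component's planted category is unambiguous under the gene (>= 80
#' identity, >= 80 coverage) and TE (> 70 identity, >= 80 coverage) rules.
#'
#' @param n_components number of components.
#' @param category_mix named proportions over `unique_gene`, `multi_gene`,
#'   `intergenic`, `te`, `unmapped`; must sum to 1.
#' @param n_genes size of the simulated gene universe (components planted as
#'   `unique_gene` draw their gene from it, so several components can share
#'   a gene, as assembler components of one gene do).
#' @param n_te_families size of the simulated TE-family universe.
#' @param seed integer seed.
#' @return list with `records` (alignment-record data.frame), `components`
#'   (all component ids, including record-less ones) and `truth`
#'   (planted category, and planted gene/family where applicable).
#' @export
simulate_alignment_records <- function(n_components,
                                       category_mix = c(unique_gene = 0.51,
                                                        multi_gene = 0.10,
                                                        intergenic = 0.35,
                                                        te = 0.01,
                                                        unmapped = 0.03),
                                       n_genes = max(1L, ceiling(n_components / 2)),
                                       n_te_families = 69L,
                                       seed = 1L) {
  cats <- c("unique_gene", "multi_gene", "intergenic", "te", "unmapped")
  mix <- setNames(numeric(length(cats)), cats)
  if (is.null(names(category_mix)) || !all(names(category_mix) %in% cats))
    stop("category_mix must be named with: ", paste(cats, collapse = ", "))
  mix[names(category_mix)] <- category_mix
  if (abs(sum(mix) - 1) > 1e-9) stop("category_mix proportions must sum to 1")
  set.seed(seed)
  category <- sample(rep(cats, .category_counts(mix, n_components)))
  comp <- sprintf("comp%06d", seq_len(n_components))

  hi_id <- function(k) round(runif(k, 85, 100), 1)   # clears >=80 and >70
  hi_cov <- function(k) round(runif(k, 85, 100), 1)
  lo_id <- function(k) round(runif(k, 30, 75), 1)    # fails the 80 rules
  rec <- function(q, t, cls, id, cov)
    if (length(q) == 0) NULL
    else data.frame(query = q, target = t, target_class = cls,
                    identity = id, coverage = cov, stringsAsFactors = FALSE)

  gene_of <- rep(NA_character_, n_components)
  fam_of <- rep(NA_character_, n_components)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  fams <- sprintf("TEfam%03d", seq_len(n_te_families))

  is_ug <- category == "unique_gene"
  gene_of[is_ug] <- sample(genes, sum(is_ug), replace = TRUE)
  is_mg <- category == "multi_gene"
  # two guaranteed-distinct genes per multi_gene component
  g1 <- sample(seq_len(n_genes), sum(is_mg), replace = TRUE)
  g2 <- 1L + (g1 + sample(seq_len(max(n_genes - 1, 1)), sum(is_mg),
                          replace = TRUE) - 1L) %% n_genes
  is_ig <- category == "intergenic"
  is_te <- category == "te"
  fam_of[is_te] <- sample(fams, sum(is_te), replace = TRUE)
  is_um <- category == "unmapped"
  um_hit <- is_um & runif(n_components) < 0.5      # rest have no record

  records <- rbind(
    rec(comp[is_ug], gene_of[is_ug], "gene_set", hi_id(sum(is_ug)), hi_cov(sum(is_ug))),
    rec(comp[is_mg], genes[g1], "gene_set", hi_id(sum(is_mg)), hi_cov(sum(is_mg))),
    rec(comp[is_mg], genes[g2], "gene_set", hi_id(sum(is_mg)), hi_cov(sum(is_mg))),
    rec(comp[is_ig], sample(genes, sum(is_ig), replace = TRUE), "gene_set",
        lo_id(sum(is_ig)), hi_cov(sum(is_ig))),   # sub-threshold gene hit
    rec(comp[is_te], fam_of[is_te], "te_db",
        round(runif(sum(is_te), 75, 100), 1), hi_cov(sum(is_te))),
    rec(comp[!is_um], "chr1", "genome", hi_id(sum(!is_um)), hi_cov(sum(!is_um))),
    rec(comp[um_hit], "chr1", "genome", lo_id(sum(um_hit)), hi_cov(sum(um_hit))))
  records <- records[order(match(records$query, comp)), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       components = comp,
       truth = data.frame(component = comp, category = category,
                          gene = gene_of, te_family = fam_of,
                          stringsAsFactors = FALSE))
}
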