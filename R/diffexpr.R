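#' Median-of-ratios size factors
#'
#' Per-sample normalization factors estimated as the median, over features,
#' of the ratio of the sample's count to the feature's geometric mean across
#' samples. Only features whose geometric mean is positive (no zero count in
#' any sample) enter the median. The underlying assumption is that most
#' features do not change between conditions, so the median ratio tracks
#' sequencing depth rather than biology.
#'
#' @param counts integer matrix (features x samples) or a [count_matrix()].
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)           # geometric mean > 0
  if (!any(usable))
    stop("size factors undefined: no feature has positive counts in every sample")
  geo <- exp(log_geo[usable])
  sf <- apply(counts, 2, function(cnt) stats::median(cnt[usable] / geo))
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor estimated; check the count matrix")
  sf
}

#' Normalize counts by size factors
#' @param counts matrix or [count_matrix()].
#' @param sf size factors (defaults to [size_factors()] of the input).
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf, "/")
}

#' Flag features too lowly expressed in all conditions
#'
#' A feature is flagged when, in every condition, the mean normalized count
#' over that condition's replicates does not exceed `threshold`. Flagged
#' features are excluded from differential testing and from inheritance
#' classification.
#'
#' @param normalized normalized count matrix.
#' @param condition condition label per sample (column).
#' @param threshold normalized-count cutoff (default 5).
#' @return logical vector per feature.
#' @export
low_expression_filter <- function(normalized, condition, threshold = 5) {
  cond_means <- sapply(unique(condition), function(cc)
    rowMeans(normalized[, condition == cc, drop = FALSE]))
  apply(cond_means <= threshold, 1, all)
}

#' Method-of-moments NB dispersion per feature
#'
#' For each tested condition the dispersion is estimated from normalized
#' counts as `(s^2 - mean) / mean^2` (the NB relation
#' variance = mu + alpha * mu^2 solved for alpha); the two per-condition
#' estimates are pooled by a (replicates - 1)-weighted average, truncated at
#' zero and floored at 1e-8. No shrinkage toward a mean-dispersion trend is
#' applied.
#'
#' @param normalized normalized count matrix.
#' @param condition condition label per sample.
#' @param contrast the two condition labels being tested.
#' @return numeric dispersion per feature (>= 1e-8).
#' @export
estimate_dispersion <- function(normalized, condition, contrast) {
  stopifnot(length(contrast) == 2, all(contrast %in% condition))
  num <- 0
  den <- 0
  for (cc in contrast) {
    sub <- normalized[, condition == cc, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    w <- ncol(sub) - 1
    num <- num + w * a
    den <- den + w
  }
  pmax(num / den, 1e-8)
}

# Wald test for a single feature: NB GLM with log link, two-group design,
# known dispersion, log(size factor) offset. Returns c(log2fc_mle, p).
.nb_wald_one <- function(y, group_b, log_sf, alpha) {
  X <- cbind(intercept = 1, group = as.numeric(group_b))
  theta <- 1 / max(alpha, 1e-8)
  fam <- MASS::negative.binomial(theta = theta)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = log_sf,
                   control = list(maxit = 50)))
  p <- NA_real_
  beta <- fit$coefficients[2]
  if (fit$rank == 2L) {
    R <- fit$qr$qr[seq_len(2), seq_len(2), drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (!is.null(cov)) {
      se <- sqrt(cov[2, 2])
      if (is.finite(se) && se > 0)
        p <- 2 * stats::pnorm(-abs(beta / se))
    }
  }
  c(beta / log(2), p)
}

#' Negative-binomial Wald test between two conditions
#'
#' Per feature: a two-sided Wald test on the log fold change from an NB
#' generalized linear model (log link, library-size offsets, the supplied
#' dispersion). P-values are then BH-adjusted across tested features. The
#' reported fold change is the ratio of normalized condition means with a
#' pseudocount of 0.5 added to each mean; `log2fc` is signed toward the
#' second condition of the contrast. Features flagged low-expressed are
#' carried through untested (p and fdr NA). Features with zero counts in
#' both conditions get p = 1, fold change 1.
#'
#' @param cm a [count_matrix()].
#' @param contrast character of length 2: the reference condition A and the
#'   condition B the log2 fold change points toward.
#' @param sf size factors; default computed on the full matrix so the three
#'   pairwise contrasts of an inheritance analysis share one normalization.
#' @param dispersions per-feature dispersions; default method-of-moments on
#'   the contrasted conditions.
#' @param low_expressed logical per feature; default the all-condition
#'   low-expression filter at `low_threshold`.
#' @param low_threshold normalized-count cutoff for the default filter.
#' @return data.frame (one row per feature): `feature`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2fc`, `pvalue`, `fdr`, `low_expressed`.
#' @export
nb_test <- function(cm, contrast, sf = NULL, dispersions = NULL,
                    low_expressed = NULL, low_threshold = 5) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  if (!all(contrast %in% cm$condition))
    stop("contrast conditions absent from design: ",
         paste(setdiff(contrast, cm$condition), collapse = ", "))
  for (cc in contrast)
    if (sum(cm$condition == cc) < 2)
      stop("condition '", cc, "' has fewer than 2 replicates")
  if (is.null(sf)) sf <- size_factors(cm)
  norm <- normalize_counts(cm, sf)
  if (is.null(low_expressed))
    low_expressed <- low_expression_filter(norm, cm$condition, low_threshold)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(norm, cm$condition, contrast)

  ia <- condition_cols(cm, contrast[1])
  ib <- condition_cols(cm, contrast[2])
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  ratio <- (mean_b + 0.5) / (mean_a + 0.5)
  fold_change <- pmax(ratio, 1 / ratio)
  log2fc <- log2(ratio)

  cols <- c(ia, ib)
  y_all <- cm$counts[, cols, drop = FALSE]
  group_b <- cm$condition[cols] == contrast[2]
  log_sf <- log(sf[cols])
  n <- nrow(y_all)
  pvalue <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (low_expressed[i]) next
    y <- y_all[i, ]
    if (all(y == 0)) {
      pvalue[i] <- 1
      fold_change[i] <- 1
      log2fc[i] <- 0
      next
    }
    res <- .nb_wald_one(y, group_b, log_sf, dispersions[i])
    pvalue[i] <- if (is.na(res[2])) 1 else res[2]
  }
  fdr <- rep(NA_real_, n)
  tested <- !low_expressed
  fdr[tested] <- stats::p.adjust(pvalue[tested], method = "BH")
  data.frame(feature = rownames(cm$counts),
             mean_a = mean_a, mean_b = mean_b,
             fold_change = fold_change, log2fc = log2fc,
             pvalue = pvalue, fdr = fdr,
             low_expressed = low_expressed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the joint FDR / fold-change significance rule
#'
#' A feature is significantly differentially expressed only when both
#' criteria hold: the BH-adjusted p-value is strictly below `fdr_thresh`
#' and the fold change is strictly above `fc_thresh`. If either criterion
#' fails, expression is considered not different between the conditions.
#'
#' @param results output of [nb_test()].
#' @param fdr_thresh FDR cutoff (default 0.01, strict `<`).
#' @param fc_thresh fold-change cutoff (default 1.5, strict `>`).
#' @return `results` with a logical `significant` column (low-expressed or
#'   untested features are FALSE).
#' @export
call_significant <- function(results, fdr_thresh = 0.01, fc_thresh = 1.5) {
  sig <- !is.na(results$fdr) &
    results$fdr < fdr_thresh &
    results$fold_change > fc_thresh &
    !results$low_expressed
  results$significant <- sig
  results
}

#' One-call differential expression between two conditions
#'
#' Convenience wrapper: size factors on the full matrix, all-condition
#' low-expression filter, method-of-moments dispersions, NB Wald test, BH
#' correction and the joint significance rule.
#'
#' @inheritParams nb_test
#' @inheritParams call_significant
#' @return annotated results data.frame (see [nb_test()],
#'   [call_significant()]).
#' @export
de_test <- function(cm, contrast, fdr_thresh = 0.01, fc_thresh = 1.5,
                    low_threshold = 5, sf = NULL) {
  res <- nb_test(cm, contrast, sf = sf, low_threshold = low_threshold)
  call_significant(res, fdr_thresh = fdr_thresh, fc_thresh = fc_thresh)
}
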