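#' Classify expression inheritance of hybrid features
#'
#' Assigns each feature one of six expression-inheritance patterns from the
#' three pairwise differential-expression comparisons (parent1 vs parent2,
#' hybrid vs parent1, hybrid vs parent2), each called with the joint
#' FDR/fold-change rule. Decision order:
#'
#' 1. `over_dominant`: hybrid significantly above both parents;
#' 2. `under_dominant`: hybrid significantly below both parents;
#' 3. `conserved`: none of the three comparisons significant;
#' 4. `p1_dominant`: parents differ, hybrid not different from parent 1 but
#'    different from parent 2;
#' 5. `p2_dominant`: the symmetric case;
#' 6. `additive`: parents differ, hybrid differs from both, and the hybrid
#'    mean lies strictly between the parental means;
#' 7. anything else: `ambiguous`.
#'
#' Over/under-dominance is tested before dominance so "significantly higher
#' than both parents" wins even when the parents also differ. The six
#' published patterns do not cover all significance/sign combinations, so
#' an explicit `ambiguous` bin preserves the partition. Low-expressed
#' features are labelled `low_expression` and not classified.
#'
#' @param de_p1p2 [de_test()] results with contrast (parent1, parent2).
#' @param de_hp1 results with contrast (parent1, hybrid): `log2fc` > 0
#'   means the hybrid is higher than parent 1.
#' @param de_hp2 results with contrast (parent2, hybrid).
#' @param hybrid label recorded in the output ("A" or "B").
#' @return data.frame per feature: `feature`, `hybrid`, `category`, the
#'   three significance flags and signed log2 fold changes, and the
#'   normalized means used for the betweenness check.
#' @export
classify_inheritance <- function(de_p1p2, de_hp1, de_hp2, hybrid = "A") {
  if (!identical(de_p1p2$feature, de_hp1$feature) ||
      !identical(de_p1p2$feature, de_hp2$feature))
    stop("the three DE results must cover the same features in the same order")
  for (d in list(de_p1p2, de_hp1, de_hp2))
    if (is.null(d$significant))
      stop("DE results must carry significance calls (run call_significant)")

  low <- de_p1p2$low_expressed | de_hp1$low_expressed | de_hp2$low_expressed
  s12 <- de_p1p2$significant
  sh1 <- de_hp1$significant     # hybrid vs parent1
  sh2 <- de_hp2$significant     # hybrid vs parent2
  up1 <- de_hp1$log2fc > 0      # hybrid above parent1
  up2 <- de_hp2$log2fc > 0
  m_p1 <- de_hp1$mean_a
  m_p2 <- de_hp2$mean_a
  m_h <- de_hp1$mean_b
  between <- (m_h > pmin(m_p1, m_p2)) & (m_h < pmax(m_p1, m_p2))

  category <- rep("ambiguous", length(s12))
  category[s12 & sh1 & sh2 & between] <- "additive"
  category[s12 & sh1 & !sh2] <- "p2_dominant"
  category[s12 & !sh1 & sh2] <- "p1_dominant"
  category[!s12 & !sh1 & !sh2] <- "conserved"
  category[sh1 & up1 & sh2 & up2] <- "over_dominant"
  category[sh1 & !up1 & sh2 & !up2] <- "under_dominant"
  category[low] <- "low_expression"

  data.frame(feature = de_p1p2$feature, hybrid = hybrid, category = category,
             sig_p1p2 = s12, sig_hp1 = sh1, sig_hp2 = sh2,
             log2fc_p1p2 = de_p1p2$log2fc, log2fc_hp1 = de_hp1$log2fc,
             log2fc_hp2 = de_hp2$log2fc,
             mean_p1 = m_p1, mean_p2 = m_p2, mean_hybrid = m_h,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize inheritance calls across the two reciprocal hybrids
#'
#' @param calls_a,calls_b [classify_inheritance()] outputs for hybrids A
#'   and B on a shared feature set.
#' @return list with `counts` (category x hybrid table including
#'   proportions of classified features) and `overlap`: per category, the
#'   fraction of hybrid-A features of that category that carry the same
#'   category in hybrid B.
#' @export
summarize_inheritance <- function(calls_a, calls_b) {
  if (!setequal(calls_a$feature, calls_b$feature))
    stop("the two hybrids must be classified on the same feature set")
  calls_b <- calls_b[match(calls_a$feature, calls_b$feature), ]
  cats <- c("conserved", "additive", "p1_dominant", "p2_dominant",
            "over_dominant", "under_dominant", "ambiguous", "low_expression")
  na <- table(factor(calls_a$category, levels = cats))
  nb <- table(factor(calls_b$category, levels = cats))
  tested_a <- sum(na[setdiff(cats, "low_expression")])
  tested_b <- sum(nb[setdiff(cats, "low_expression")])
  counts <- data.frame(category = cats,
                       n_hybridA = as.integer(na), n_hybridB = as.integer(nb),
                       prop_hybridA = ifelse(cats == "low_expression", NA,
                                             as.integer(na) / tested_a),
                       prop_hybridB = ifelse(cats == "low_expression", NA,
                                             as.integer(nb) / tested_b),
                       stringsAsFactors = FALSE)
  overlap <- sapply(cats, function(cc) {
    in_a <- calls_a$category == cc
    if (!any(in_a)) return(NA_real_)
    sum(in_a & calls_b$category == cc) / sum(in_a)
  })
  list(counts = counts, overlap = overlap)
}
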