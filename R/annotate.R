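#' Classify assembled components into annotation categories
#'
#' Applies the identity/coverage rules used to annotate a de novo
#' co-assembled transcriptome against a reference: a hit to the gene set or
#' genome qualifies at >= 80% identity and >= 80% query coverage (inclusive),
#' a hit to the TE database at identity strictly above 70% and coverage
#' >= 80%. Per component: exactly one qualifying gene -> `unique_gene`;
#' two or more distinct qualifying genes -> `multi_gene`; no qualifying gene
#' but a qualifying TE hit -> `te` (best family by identity, ties broken
#' lexicographically); otherwise a qualifying genome hit -> `intergenic`;
#' otherwise `unmapped`. Precedence is gene > TE > intergenic. Components
#' listed in `components` with no record at all are `unmapped`.
#'
#' @param records alignment-record data.frame (`query`, `target`,
#'   `target_class` in gene_set/genome/te_db, `identity`, `coverage`).
#' @param components optional character vector of all component ids
#'   (defaults to the queries present in `records`).
#' @param gene_id_thresh,gene_cov_thresh inclusive gene/genome thresholds.
#' @param te_id_thresh exclusive TE identity threshold.
#' @param te_cov_thresh inclusive TE coverage threshold.
#' @return data.frame with `component`, `category` and `target` (the gene id
#'   for `unique_gene`, TE family for `te`, NA otherwise); the categories
#'   partition the component set.
#' @export
classify_components <- function(records, components = NULL,
                                gene_id_thresh = 80, gene_cov_thresh = 80,
                                te_id_thresh = 70, te_cov_thresh = 80) {
  if (is.null(components)) components <- unique(records$query)
  if (length(components) == 0) stop("no components to classify")

  gene_q <- records[records$target_class == "gene_set" &
                    records$identity >= gene_id_thresh &
                    records$coverage >= gene_cov_thresh, , drop = FALSE]
  te_q <- records[records$target_class == "te_db" &
                  records$identity > te_id_thresh &
                  records$coverage >= te_cov_thresh, , drop = FALSE]
  genome_q <- records[records$target_class == "genome" &
                      records$identity >= gene_id_thresh &
                      records$coverage >= gene_cov_thresh, , drop = FALSE]

  # distinct genes per component: two hits to one gene are still unique_gene
  gene_u <- unique(gene_q[, c("query", "target")])
  n_genes <- table(gene_u$query)
  single <- gene_u[gene_u$query %in% names(n_genes)[n_genes == 1L], ]
  gene_of <- setNames(single$target, single$query)
  # best TE family: highest identity, lexicographic tie-break
  best_te <- character(0)
  if (nrow(te_q) > 0) {
    t1 <- te_q[order(te_q$query, -te_q$identity, te_q$target), , drop = FALSE]
    t1 <- t1[!duplicated(t1$query), , drop = FALSE]
    best_te <- setNames(t1$target, t1$query)
  }

  ng <- as.integer(n_genes[match(components, names(n_genes))])
  ng[is.na(ng)] <- 0L
  te_target <- best_te[match(components, names(best_te))]
  category <- rep("unmapped", length(components))
  category[components %in% unique(genome_q$query)] <- "intergenic"
  category[!is.na(te_target)] <- "te"
  category[ng >= 2L] <- "multi_gene"
  category[ng == 1L] <- "unique_gene"
  target <- rep(NA_character_, length(components))
  target[category == "te"] <- te_target[category == "te"]
  target[category == "unique_gene"] <-
    gene_of[components[category == "unique_gene"]]
  data.frame(component = components, category = category, target = target,
             stringsAsFactors = FALSE)
}

#' Cluster annotated components into gene/TE-family features
#'
#' Components assigned to the same gene (or the same TE family) have their
#' counts summed per sample; `multi_gene`, `intergenic` and `unmapped`
#' components are kept as singleton features. The per-sample grand total of
#' counts is conserved.
#'
#' @param annotations output of [classify_components()].
#' @param cm a [count_matrix()] of per-component counts; every component in
#'   `cm` must be annotated.
#' @return a feature-level [count_matrix()].
#' @export
cluster_to_features <- function(annotations, cm) {
  missing_ann <- setdiff(rownames(cm$counts), annotations$component)
  if (length(missing_ann) > 0)
    stop("components without annotation: ", paste(utils::head(missing_ann), collapse = ", "))
  ann <- annotations[match(rownames(cm$counts), annotations$component), ]
  feature <- ifelse(ann$category %in% c("unique_gene", "te") & !is.na(ann$target),
                    ann$target, ann$component)
  summed <- rowsum(cm$counts, group = feature, reorder = FALSE)
  storage.mode(summed) <- "integer"
  count_matrix(summed, setNames(cm$condition, colnames(cm$counts)))
}

#' Fraction of chimera-candidate components
#'
#' Components with no qualifying alignment to the reference genome are
#' assembly chimera candidates; their fraction is a co-assembly QC metric.
#'
#' @param annotations output of [classify_components()].
#' @return `#unmapped / #components`, in `[0, 1]`.
#' @export
chimera_fraction <- function(annotations) {
  if (nrow(annotations) == 0) stop("chimera fraction undefined on an empty annotation set")
  sum(annotations$category == "unmapped") / nrow(annotations)
}

#' Associate single-assembly components with co-assembly components
#'
#' A co-assembly component is "associated" when at least one single-assembly
#' component aligns to it at >= `id_thresh` identity and >= `cov_thresh`
#' query coverage; the rest would be lost by single-species assembly.
#'
#' @param hits alignment records; queries are single-assembly components,
#'   targets are co-assembly components.
#' @param coassembly_components character vector of all co-assembly
#'   component ids.
#' @param id_thresh,cov_thresh inclusive association thresholds.
#' @return list with `n_associated` and `n_lost`.
#' @export
associate_assemblies <- function(hits, coassembly_components,
                                 id_thresh = 80, cov_thresh = 80) {
  q <- hits[hits$identity >= id_thresh & hits$coverage >= cov_thresh, , drop = FALSE]
  assoc <- intersect(coassembly_components, unique(q$target))
  list(n_associated = length(assoc),
       n_lost = length(coassembly_components) - length(assoc))
}
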