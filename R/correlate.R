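#' Pearson correlation with Fisher-z confidence interval and t-test
#'
#' Computes Pearson's r between paired per-TE values, a 95% confidence
#' interval via the Fisher z-transform (atanh(r) +/- 1.96/sqrt(n-3), back-
#' transformed), and the two-sided t-test on n - 2 degrees of freedom
#' (t = r * sqrt((n-2)/(1-r^2))). With |r| = 1 the interval is degenerate
#' and flagged rather than computed.
#'
#' @param x,y paired numeric vectors (n >= 4 for a CI).
#' @param log_transform apply log2 to both inputs before correlating
#'   (for ratio inputs; values must then be positive).
#' @param conf normal quantile coverage (default 95%, quantile 1.96).
#' @return object of class `correlation_report`: `n`, `r`, `ci_low`,
#'   `ci_high`, `t`, `p_value`, `degenerate`.
#' @export
correlate <- function(x, y, log_transform = FALSE, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (log_transform) {
    x <- log2(x)
    y <- log2(y)
  }
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("non-finite values after transform")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs for a Fisher confidence interval")
  r <- stats::cor(x, y)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  if (abs(r) >= 1 - 1e-12) {
    return(structure(list(n = n, r = r, ci_low = r, ci_high = r,
                          t = Inf * sign(r), p_value = 0, degenerate = TRUE),
                     class = "correlation_report"))
  }
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * q / sqrt(n - 3))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  structure(list(n = n, r = r, ci_low = ci[1], ci_high = ci[2],
                 t = tt, p_value = 2 * stats::pt(-abs(tt), df = n - 2),
                 degenerate = FALSE),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), 95%% CI [%.3f; %.3f], t = %.3f, p = %.4g%s\n",
              x$r, x$n, x$ci_low, x$ci_high, x$t, x$p_value,
              if (x$degenerate) " [degenerate CI]" else ""))
  invisible(x)
}

#' Between-hybrid TE expression vs piRNA ratio table
#'
#' Builds the paired table correlating, per TE family, the log2 ratio of TE
#' expression between the two reciprocal hybrids against the log2 ratio of
#' their (per-million, optionally secondary-only) piRNA counts. A 0.5
#' pseudocount keeps families with zero piRNAs in the table. Families
#' missing on either side are dropped and their number recorded.
#'
#' @param expr_a,expr_b named per-TE normalized expression means for
#'   hybrids A and B.
#' @param pirna_a,pirna_b named per-TE piRNA counts (per-million scale;
#'   pass secondary-only counts for the secondary mode).
#' @param pseudocount added to every value before forming ratios.
#' @return data.frame with `te`, `expr_ratio` (log2 A/B expression) and
#'   `pirna_ratio` (log2 A/B piRNA); attribute `n_dropped`.
#' @export
te_pirna_ratio_table <- function(expr_a, expr_b, pirna_a, pirna_b,
                                 pseudocount = 0.5) {
  common <- Reduce(intersect, list(names(expr_a), names(expr_b),
                                   names(pirna_a), names(pirna_b)))
  all_ids <- unique(c(names(expr_a), names(expr_b),
                      names(pirna_a), names(pirna_b)))
  if (length(common) == 0) stop("no TE family present in all four inputs")
  out <- data.frame(
    te = common,
    expr_ratio = log2((expr_a[common] + pseudocount) /
                      (expr_b[common] + pseudocount)),
    pirna_ratio = log2((pirna_a[common] + pseudocount) /
                       (pirna_b[common] + pseudocount)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- length(all_ids) - length(common)
  out
}
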