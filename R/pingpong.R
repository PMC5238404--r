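#' 5' overlap histogram of sense/antisense small-RNA pairs
#'
#' For every pair of a plus-strand and a minus-strand read on the same TE
#' consensus, the overlap of their 5' ends is
#' `o = (5' position of the minus read) - (5' position of the plus read) + 1`
#' (1-based inclusive: a minus 5' end sitting on the plus 5' position is an
#' overlap of 1). Pairs with `o` between 1 and `max_overlap` are counted,
#' each unordered pair once. Ping-pong amplification produces an excess of
#' pairs at exactly o = 10.
#'
#' The count for each overlap is accumulated from position tallies (product
#' of the number of plus 5' ends at x and minus 5' ends at x + o - 1), which
#' is equivalent to the quadratic loop over all read pairs.
#'
#' @param reads a [smallrna_reads()] set (lengths already filtered).
#' @param te_id consensus to analyze.
#' @param max_overlap largest overlap tallied (default 26).
#' @return object of class `overlap_histogram`: `te`, `overlap` (1..max),
#'   `counts`, `total`.
#' @export
overlap_histogram <- function(reads, te_id, max_overlap = 26) {
  sub <- reads[reads$consensus == te_id, , drop = FALSE]
  p5 <- sub$five_prime[sub$strand == "+"]
  m5 <- sub$five_prime[sub$strand == "-"]
  counts <- numeric(max_overlap)
  if (length(p5) > 0 && length(m5) > 0) {
    tp <- table(p5)
    tm <- table(m5)
    xp <- as.integer(names(tp))
    np <- as.numeric(tp)
    tm_n <- as.numeric(tm)
    names(tm_n) <- names(tm)
    for (o in seq_len(max_overlap)) {
      hit <- tm_n[as.character(xp + o - 1L)]
      counts[o] <- sum(np * hit, na.rm = TRUE)
    }
  }
  structure(list(te = te_id, overlap = seq_len(max_overlap),
                 counts = counts, total = sum(counts)),
            class = "overlap_histogram")
}

#' Ping-pong signature of an overlap histogram
#'
#' The signature is summarized by `z10`, the z-score of the pair count at a
#' 10-nt overlap against the counts at all other overlaps, and `fraction10`,
#' the share of pairs overlapping by exactly 10 nt (the height of the peak
#' indicates the proportion of piRNAs engaged in the ping-pong cycle).
#' When the off-peak counts have zero spread, `z10` is undefined and
#' reported as NA with `degenerate = TRUE`.
#'
#' @param hist an [overlap_histogram()] with at least one pair.
#' @return list with `te`, `z10`, `fraction10`, `argmax` (overlap with the
#'   highest count) and `degenerate`.
#' @export
pingpong_signature <- function(hist) {
  stopifnot(inherits(hist, "overlap_histogram"))
  if (hist$total < 1) stop("ping-pong signature undefined on an empty histogram")
  at10 <- hist$overlap == 10
  if (!any(at10)) stop("histogram does not cover a 10-nt overlap")
  off <- hist$counts[!at10]
  s <- stats::sd(off)
  num <- hist$counts[at10] - mean(off)
  # a perfectly flat histogram has no excess at 10: z is 0, not 0/0
  z10 <- if (is.na(s) || s == 0) {
    if (isTRUE(all.equal(num, 0))) 0 else NA_real_
  } else num / s
  list(te = hist$te,
       z10 = z10,
       fraction10 = hist$counts[at10] / hist$total,
       argmax = hist$overlap[which.max(hist$counts)],
       degenerate = is.na(z10))
}

#' Count piRNAs and secondary piRNAs on a TE consensus
#'
#' A read is counted as a secondary piRNA when it participates in at least
#' one opposite-strand pair whose 5' ends overlap by exactly 10 nt (the
#' ping-pong product definition). Normalized counts are reads per million
#' mapped piRNAs; the denominator defaults to all retained reads in the set
#' across all TEs.
#'
#' @param reads a [smallrna_reads()] set.
#' @param te_id consensus to analyze.
#' @param library_size per-million denominator (default `nrow(reads)`).
#' @return list: `te`, `total`, `secondary`, `total_per_million`,
#'   `secondary_per_million`, `library_size`.
#' @export
count_secondary <- function(reads, te_id, library_size = NULL) {
  if (is.null(library_size)) library_size <- nrow(reads)
  sub <- reads[reads$consensus == te_id, , drop = FALSE]
  plus <- sub$strand == "+"
  p5 <- sub$five_prime[plus]
  m5 <- sub$five_prime[!plus]
  sec_plus <- p5 %in% (m5 - 9L)    # a minus 5' end 9 nt downstream => o = 10
  sec_minus <- m5 %in% (p5 + 9L)
  secondary <- sum(sec_plus) + sum(sec_minus)
  total <- nrow(sub)
  per_m <- function(x) if (library_size > 0) x * 1e6 / library_size else NA_real_
  list(te = te_id, total = total, secondary = secondary,
       total_per_million = per_m(total),
       secondary_per_million = per_m(secondary),
       library_size = library_size)
}

#' Strand-resolved per-base read coverage of a TE consensus
#'
#' @param reads a [smallrna_reads()] set.
#' @param consensus_length length of the consensus in nt.
#' @param te_id consensus to profile.
#' @return list with numeric vectors `plus` and `minus` of length
#'   `consensus_length` (position i = consensus base i, 1-based).
#' @export
coverage_profile <- function(reads, consensus_length, te_id) {
  sub <- reads[reads$consensus == te_id, , drop = FALSE]
  if (nrow(sub) > 0 && (any(sub$start < 0) || any(sub$end > consensus_length)))
    stop("read outside consensus bounds; ingest should have rejected it")
  cover <- function(df) {
    v <- numeric(consensus_length)
    if (nrow(df) > 0) {
      # difference-array accumulation over 0-based half-open intervals
      d <- numeric(consensus_length + 1)
      for (i in seq_len(nrow(df))) {
        d[df$start[i] + 1] <- d[df$start[i] + 1] + 1
        d[df$end[i] + 1] <- d[df$end[i] + 1] - 1
      }
      v <- cumsum(d[seq_len(consensus_length)])
    }
    v
  }
  list(plus = cover(sub[sub$strand == "+", , drop = FALSE]),
       minus = cover(sub[sub$strand == "-", , drop = FALSE]))
}
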