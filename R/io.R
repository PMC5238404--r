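#' Construct a validated count matrix
#'
#' The central container for raw read counts: an integer matrix (features x
#' samples) plus a sample-to-condition map. Counts must be raw: the
#' median-of-ratios normalization downstream assumes untransformed integers,
#' so non-integer or negative cells are fatal, not coerced.
#'
#' @param counts numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required); non-negative integers only.
#' @param condition named character vector mapping every sample (column)
#'   to a condition label.
#' @return an object of class `count_matrix`: list with `counts` (integer
#'   matrix) and `condition`.
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique feature ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at feature '%s', sample '%s': %s (raw non-negative integers required)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 counts[bad[1, 1], bad[1, 2]]))
  if (is.null(names(condition))) stop("condition must be named by sample id")
  missing_samp <- setdiff(colnames(counts), names(condition))
  if (length(missing_samp) > 0)
    stop("samples absent from design: ", paste(missing_samp, collapse = ", "))
  condition <- condition[colnames(counts)]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 condition = as.character(condition)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Samples belonging to a condition
#' @param cm a `count_matrix`.
#' @param cond condition label.
#' @return column indices of the condition's samples.
#' @keywords internal
condition_cols <- function(cm, cond) which(cm$condition == cond)

#' Read a raw count table and its design
#'
#' The count table is a TSV with a header row: first column feature ids,
#' remaining columns one per sample. The design TSV has two columns,
#' `sample` and `condition`, and must cover every sample column.
#' Validation is strict: negative, non-integer or missing cells are fatal
#' with their coordinates; row order is preserved.
#'
#' @param path count TSV path.
#' @param design_path design TSV path.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path, design_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs a feature column plus >=1 sample")
  feats <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric count at row %d ('%s'), column '%s'",
                 bad[1, 1], feats[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  rownames(mat) <- feats
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% colnames(design)))
    stop("design must have columns 'sample' and 'condition'")
  count_matrix(mat, setNames(design$condition, design$sample))
}

#' Write a count matrix and its design as TSV
#'
#' @param cm a [count_matrix()].
#' @param path count TSV destination.
#' @param design_path design TSV destination (skipped if NULL).
#' @return invisibly, `path`.
#' @export
write_count_table <- function(cm, path, design_path = NULL) {
  df <- data.frame(feature = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    utils::write.table(data.frame(sample = colnames(cm$counts),
                                  condition = cm$condition),
                       design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated small-RNA read set
#'
#' Coordinates are 0-based half-open on the TE consensus. The 5' end of a
#' plus-strand read is its start; the 5' end of a minus-strand read is its
#' highest coordinate (`end - 1`). The 5' position is computed once here so
#' the overlap engine never re-derives strand conventions.
#'
#' @param df data.frame with columns `consensus`, `start`, `end`,
#'   `read_id`, `length`, `strand`.
#' @return a `smallrna_reads` data.frame with an extra `five_prime` column.
#' @export
smallrna_reads <- function(df) {
  need <- c("consensus", "start", "end", "read_id", "length", "strand")
  if (!all(need %in% colnames(df)))
    stop("small-RNA reads need columns: ", paste(need, collapse = ", "))
  if (nrow(df) > 0) {
    if (any(df$length <= 0)) stop("read lengths must be > 0")
    if (any(df$end - df$start != df$length))
      stop("end - start must equal length (0-based half-open coordinates)")
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(df$start < 0)) stop("negative start coordinate")
  }
  df$five_prime <- ifelse(df$strand == "+", df$start, df$end - 1L)
  class(df) <- c("smallrna_reads", "data.frame")
  df
}

#' Read mapped small-RNA reads from BED6 or minimal SAM
#'
#' Retains only reads whose length is within `[length_min, length_max]`
#' (piRNA-sized, 23-29 nt by default) and reports how many were discarded.
#' BED input is 6 columns (consensus, start, end, name, score-or-length,
#' strand; 0-based half-open). SAM input is plain text with header lines and
#' ungapped mapped records; the reverse flag (0x10) marks minus-strand reads
#' whose 5' end is the alignment end. If `consensus_lengths` is given
#' (named vector, e.g. from a consensus FASTA), out-of-bounds reads are
#' fatal.
#'
#' @param path BED or SAM path; format chosen by extension (`.sam` = SAM).
#' @param length_min,length_max inclusive retained length bounds.
#' @param consensus_lengths optional named lengths for bounds checking.
#' @return a [smallrna_reads()] set; attribute `n_discarded` counts
#'   length-filtered reads.
#' @export
read_smallrna <- function(path, length_min = 23, length_max = 29,
                          consensus_lengths = NULL) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    lines <- readLines(path)
    body_idx <- which(!startsWith(lines, "@"))
    recs <- lapply(body_idx, function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) < 11) stop("malformed SAM record at line ", i)
      flag <- suppressWarnings(as.integer(f[2]))
      pos <- suppressWarnings(as.integer(f[4]))
      if (is.na(flag) || is.na(pos)) stop("malformed SAM record at line ", i)
      if (bitwAnd(flag, 4L) != 0L) return(NULL)       # unmapped
      len <- nchar(f[10])
      if (!grepl("^[0-9]+M$", f[6]))
        stop("only ungapped (xM) alignments supported, line ", i)
      data.frame(consensus = f[3], start = pos - 1L, end = pos - 1L + len,
                 read_id = f[1], length = len,
                 strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
  } else {
    df <- tryCatch(
      utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("consensus", "start", "end",
                                      "read_id", "score", "strand")),
      error = function(e) NULL)
    if (!is.null(df) && nrow(df) > 0) {
      if (!is.numeric(df$start) || !is.numeric(df$end) ||
          !all(df$strand %in% c("+", "-")))
        stop("malformed BED record in ", path)
      df$length <- df$end - df$start
      df <- df[, c("consensus", "start", "end", "read_id", "length", "strand")]
    }
  }
  if (is.null(df) || nrow(df) == 0) {
    warning("no reads in ", path)
    empty <- data.frame(consensus = character(), start = integer(),
                        end = integer(), read_id = character(),
                        length = integer(), strand = character(),
                        stringsAsFactors = FALSE)
    out <- smallrna_reads(empty)
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  keep <- df$length >= length_min & df$length <= length_max
  n_disc <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(consensus_lengths)) {
    lim <- consensus_lengths[df$consensus]
    if (any(is.na(lim)))
      stop("reads on consensus absent from FASTA: ",
           paste(unique(df$consensus[is.na(lim)]), collapse = ", "))
    if (any(df$end > lim | df$start < 0))
      stop("read coordinates outside consensus bounds")
  }
  out <- smallrna_reads(df)
  attr(out, "n_discarded") <- n_disc
  out
}

#' Write small-RNA reads as BED6
#'
#' @param reads a [smallrna_reads()] set.
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_smallrna_bed <- function(reads, path) {
  utils::write.table(
    data.frame(reads$consensus, reads$start, reads$end,
               reads$read_id, reads$length, reads$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read alignment records (query/target/class/identity/coverage TSV)
#'
#' @param path TSV with columns query, target, target_class, identity,
#'   coverage.
#' @return validated data.frame of alignment records.
#' @export
read_alignment_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query", "target", "target_class", "identity", "coverage")
  if (!all(need %in% colnames(df)))
    stop("alignment table needs columns: ", paste(need, collapse = ", "))
  bad <- which(df$identity < 0 | df$identity > 100 |
               df$coverage < 0 | df$coverage > 100)
  if (length(bad) > 0)
    stop("identity/coverage outside [0,100] at row ", bad[1])
  df
}

#' Write alignment records as TSV
#' @param records alignment-record data.frame.
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_alignment_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequence lengths from a FASTA file
#'
#' Minimal single-pass FASTA reader used for consensus bounds checking and
#' coverage profiles; multi-line sequences are supported.
#'
#' @param path FASTA path.
#' @return named integer vector of sequence lengths.
#' @export
read_fasta_lengths <- function(path) {
  lines <- readLines(path)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("no FASTA headers in ", path)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  lens <- tapply(nchar(lines[!hdr]), grp[!hdr], sum)
  out <- integer(length(ids))
  names(out) <- ids
  out[as.integer(names(lens))] <- as.integer(lens)
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}
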