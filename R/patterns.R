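# Second processing pass: re-align merged reads to the template, score each
# read's binary methylation pattern at the expected CpG columns, and tabulate
# unique patterns per amplicon and sample.

pattern_matrix <- function(patterns) {
  if (!length(patterns)) return(matrix(integer(0), 0, 0))
  matrix(as.integer(unlist(strsplit(patterns, "", fixed = TRUE))),
         nrow = length(patterns), byrow = TRUE)
}

# Base observed at given 0-based template positions, from one gapped alignment.
# Returns a character vector with "" for positions outside the aligned span or
# opposite an aligner gap.
bases_at_positions <- function(read_aln, tmpl_aln, start, positions) {
  cols <- aln_columns(read_aln, tmpl_aln, start)
  coord <- start + cumsum(cols$tmpl != "-") - 1L
  out <- character(length(positions))
  for (k in seq_along(positions)) {
    hit <- which(cols$tmpl != "-" & coord == positions[k])
    out[k] <- if (length(hit) == 1L && cols$read[hit] != "-") cols$read[hit] else ""
  }
  out
}

#' Call the methylation pattern of one merged read
#'
#' The merged read is re-aligned to the converted template (same contract as
#' \code{\link{align_bisulfite}}), eliminating positional drift introduced by
#' read indels, and the base at every expected CpG column is scored: C gives 1
#' (methylated), T gives 0 (unmethylated). A read showing any other base, an
#' aligner gap, or not covering a CpG column is classed ambiguous as a whole.
#' Bases at declared SNP columns are recorded verbatim and never affect the
#' pattern.
#'
#' @param merged A merged-read list (from \code{\link{merge_pair}}) or a plain
#'   sequence string.
#' @param template An \code{\link{amplicon_template}}.
#' @return A list with \code{pattern} (bit string, or \code{NA} if ambiguous),
#'   \code{ambiguous}, and \code{snp_bases} (string, "." at uncovered SNPs).
#' @export
call_pattern <- function(merged, template) {
  seq <- if (is.list(merged)) merged$sequence else merged
  a <- align_bisulfite(seq, template$converted_seq)
  cpg <- bases_at_positions(a$read_aln, a$template_aln, a$start, template$cpg_positions)
  bits <- ifelse(cpg == "C", "1", ifelse(cpg == "T", "0", NA_character_))
  ambiguous <- anyNA(bits)
  snp <- if (length(template$snp_positions)) {
    b <- bases_at_positions(a$read_aln, a$template_aln, a$start, template$snp_positions)
    paste(ifelse(b == "", ".", b), collapse = "")
  } else ""
  list(pattern = if (ambiguous) NA_character_ else paste(bits, collapse = ""),
       ambiguous = ambiguous, snp_bases = snp)
}

#' Call methylation patterns for a batch of merged reads
#'
#' Batch version of \code{\link{call_pattern}}: every merged read is re-aligned
#' to the template (reads compatible with the template without mismatch at
#' their expected offset take the gap-free shortcut of the aligner) and scored
#' at the CpG columns.
#'
#' @param sequences Character vector of merged, filter-passing sequences.
#' @param template An \code{\link{amplicon_template}}.
#' @param tstart Optional 0-based template offsets used as alignment anchors.
#' @return A list with \code{pattern} (character, \code{NA} where ambiguous),
#'   \code{snp_bases}, \code{n_called}, \code{n_ambiguous}.
#' @export
call_patterns <- function(sequences, template, tstart = NULL) {
  n <- length(sequences)
  J <- length(template$cpg_positions)
  if (n == 0L) {
    return(list(pattern = character(0), snp_bases = character(0),
                n_called = 0L, n_ambiguous = 0L))
  }
  anchors <- if (is.null(tstart)) rep(NA_integer_, n) else as.integer(tstart)
  a <- align_batch(sequences, template$converted_seq, anchors = anchors)

  cpg_chars <- matrix("", n, J)
  snp_chars <- matrix(".", n, length(template$snp_positions))
  fast <- a$fast
  if (any(fast)) {
    i <- which(fast)
    s <- a$start[i]; e <- a$end[i]
    for (j in seq_len(J)) {
      p <- template$cpg_positions[j]
      covered <- p >= s & p < e
      ch <- substring(sequences[i], p - s + 1L, p - s + 1L)
      cpg_chars[i[covered], j] <- ch[covered]
    }
    for (j in seq_along(template$snp_positions)) {
      p <- template$snp_positions[j]
      covered <- p >= s & p < e
      ch <- substring(sequences[i], p - s + 1L, p - s + 1L)
      snp_chars[i[covered], j] <- ch[covered]
    }
  }
  for (i in which(!fast)) {
    cpg_chars[i, ] <- bases_at_positions(a$read_aln[i], a$template_aln[i],
                                         a$start[i], template$cpg_positions)
    if (ncol(snp_chars)) {
      b <- bases_at_positions(a$read_aln[i], a$template_aln[i], a$start[i],
                              template$snp_positions)
      snp_chars[i, ] <- ifelse(b == "", ".", b)
    }
  }
  bits <- matrix(NA_character_, n, J)
  bits[cpg_chars == "C"] <- "1"
  bits[cpg_chars == "T"] <- "0"
  ambiguous <- rowSums(is.na(bits)) > 0L
  pattern <- rep(NA_character_, n)
  if (any(!ambiguous)) {
    ok <- which(!ambiguous)
    pattern[ok] <- do.call(paste0, as.data.frame(bits[ok, , drop = FALSE],
                                                 stringsAsFactors = FALSE))
  }
  snp_bases <- if (ncol(snp_chars)) {
    do.call(paste0, as.data.frame(snp_chars, stringsAsFactors = FALSE))
  } else rep("", n)
  list(pattern = pattern, snp_bases = snp_bases,
       n_called = sum(!ambiguous), n_ambiguous = sum(ambiguous))
}

#' Tabulate unique methylation patterns
#'
#' Aggregates identical pattern strings into a per-amplicon, per-sample count
#' table, ordered by count descending then pattern string ascending.
#'
#' @param patterns Character vector of called patterns; \code{NA} entries are
#'   counted as ambiguous.
#' @param amplicon,sample Identifiers.
#' @param snp_bases Optional character vector parallel to \code{patterns}
#'   holding the raw bases at declared SNP columns.
#' @return An object of class \code{pattern_counts}: list with \code{amplicon},
#'   \code{sample}, \code{counts} (named integer vector), \code{n_called},
#'   \code{n_ambiguous}, \code{n_cpgs}, and optional \code{snp_counts}
#'   data.frame of (pattern, snp_bases, count).
#' @export
tabulate_patterns <- function(patterns, amplicon = "amplicon", sample = "sample",
                              snp_bases = NULL) {
  called <- patterns[!is.na(patterns)]
  if (length(called)) {
    nc <- unique(nchar(called))
    if (length(nc) > 1L) stop("integrity error: mixed pattern lengths in one table")
  } else nc <- 0L
  tab <- table(called)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  if (length(counts)) counts <- counts[order(-counts, names(counts))]
  snp_counts <- NULL
  if (!is.null(snp_bases) && any(nzchar(snp_bases[!is.na(patterns)]))) {
    keep <- !is.na(patterns)
    agg <- stats::aggregate(list(count = rep(1L, sum(keep))),
                            by = list(pattern = patterns[keep],
                                      snp_bases = snp_bases[keep]),
                            FUN = sum)
    snp_counts <- agg[order(-agg$count, agg$pattern, agg$snp_bases), , drop = FALSE]
    rownames(snp_counts) <- NULL
  }
  structure(list(amplicon = amplicon, sample = sample, counts = counts,
                 n_called = length(called), n_ambiguous = sum(is.na(patterns)),
                 n_cpgs = nc, snp_counts = snp_counts),
            class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, n = 10L, ...) {
  cat("Pattern counts for amplicon '", x$amplicon, "', sample '", x$sample,
      "': ", length(x$counts), " unique patterns, ", x$n_called, " called, ",
      x$n_ambiguous, " ambiguous\n", sep = "")
  if (length(x$counts)) {
    show <- head(x$counts, n)
    print(data.frame(pattern = names(show), count = unname(show)))
    if (length(x$counts) > n) cat("... and", length(x$counts) - n, "more\n")
  }
  invisible(x)
}

#' Per-CpG combined methylation levels
#'
#' The combined level of CpG j is the weighted mean of bit j over patterns,
#' weighted by normalized counts (for a \code{pattern_counts}) or estimated
#' frequencies (for a \code{\link{fit_pattern_mixture}} fit or a named numeric
#' vector of frequencies).
#'
#' @param x A \code{pattern_counts}, a \code{pattern_fit}, or a named numeric
#'   vector mapping pattern strings to weights.
#' @param ... Unused.
#' @return Numeric vector of levels in \code{[0, 1]}, one per CpG.
#' @export
per_cpg_levels <- function(x, ...) UseMethod("per_cpg_levels")

#' @export
per_cpg_levels.default <- function(x, ...) {
  if (!is.numeric(x) || is.null(names(x)) || !length(x)) {
    stop("need a nonempty named numeric vector of pattern weights")
  }
  w <- x / sum(x)
  as.numeric(crossprod(pattern_matrix(names(x)), w))
}

#' @export
per_cpg_levels.pattern_counts <- function(x, ...) {
  if (!length(x$counts)) stop("empty pattern count table")
  per_cpg_levels.default(x$counts)
}

#' Write / read a pattern counts table
#'
#' TSV with columns amplicon, sample, pattern, count; a sibling summary row set
#' records \code{n_called} and \code{n_ambiguous}.
#'
#' @param x A \code{pattern_counts}.
#' @param path Output path for the counts TSV.
#' @return \code{path}, invisibly (writer); a \code{pattern_counts} (reader).
#' @export
write_pattern_counts <- function(x, path) {
  df <- data.frame(amplicon = x$amplicon, sample = x$sample,
                   pattern = names(x$counts), count = unname(x$counts),
                   n_called = x$n_called, n_ambiguous = x$n_ambiguous)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pattern_counts
#' @export
read_pattern_counts <- function(path) {
  df <- read.delim(path, colClasses = c(pattern = "character"))
  if (!nrow(df)) stop("empty pattern counts file: ", path)
  counts <- as.integer(df$count)
  names(counts) <- df$pattern
  structure(list(amplicon = df$amplicon[1L], sample = df$sample[1L],
                 counts = counts, n_called = df$n_called[1L],
                 n_ambiguous = df$n_ambiguous[1L],
                 n_cpgs = nchar(df$pattern[1L]), snp_counts = NULL),
            class = "pattern_counts")
}
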