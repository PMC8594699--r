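# Read extraction: primer-anchored pair selection, template alignment,
# proportional overlap truncation, merging, and the length/gap quality filter.

#' Exact nested-primer match
#'
#' A read matches when its bases at 1-based positions 4-33 equal the last 30
#' nucleotides of the nested primer exactly (case-insensitive). The three
#' leading bases are skipped because library reads carry a short non-template
#' start. Reads shorter than 33 nt never match.
#'
#' @param read_seq Character vector of read sequences (sequencer orientation).
#' @param primer Primer sequence (>= 30 nt).
#' @return Logical vector.
#' @export
match_primer <- function(read_seq, primer) {
  stopifnot(nchar(primer) >= 30L)
  lp <- nchar(primer)
  last30 <- toupper(substr(primer, lp - 29L, lp))
  nchar(read_seq) >= 33L & toupper(substr(read_seq, 4L, 33L)) == last30
}

round_half_up <- function(x) floor(x + 0.5)

# Truncation coordinate per alignment column: non-gap template columns carry
# their own 0-based coordinate, insertion columns (template gap) the coordinate
# of the next template base, so an insertion at the truncation boundary falls
# on the downstream side.
aln_columns <- function(read_aln, tmpl_aln, start) {
  rc <- strsplit(read_aln, "", fixed = TRUE)[[1L]]
  tc <- strsplit(tmpl_aln, "", fixed = TRUE)[[1L]]
  nongap <- tc != "-"
  cum <- cumsum(nongap)
  list(read = rc, tmpl = tc, tc = start + cum - as.integer(nongap))
}

# Merge two span-trimmed alignments of the same template (a = list(start, end,
# read_aln, tmpl_aln); read 2 already in template orientation).
merge_aligned_pair <- function(a1, a2) {
  if (a2$end <= a1$start) return(list(rejected = "discordant"))
  v <- max(0L, min(a1$end, a2$end) - max(a1$start, a2$start))
  c1 <- aln_columns(a1$read_aln, a1$tmpl_aln, a1$start)
  c2 <- aln_columns(a2$read_aln, a2$tmpl_aln, a2$start)
  L1 <- length(c1$read)
  L2 <- length(c2$read)
  t1 <- round_half_up(v * L1 / (L1 + L2))
  t2 <- v - t1
  cut1 <- a1$end - t1
  cut2 <- a2$start + t2
  keep1 <- c1$tc < cut1
  keep2 <- c2$tc >= cut2
  r1 <- c1$read[keep1]
  r2 <- c2$read[keep2]
  aligned_len <- sum(keep1) + sum(keep2)
  gap_cols <- sum(r1 == "-") + sum(r2 == "-") +
    sum(c1$tmpl[keep1] == "-") + sum(c2$tmpl[keep2] == "-")
  seq <- paste(c(r1[r1 != "-"], r2[r2 != "-"]), collapse = "")
  list(sequence = seq,
       aligned_len = aligned_len,
       gap_fraction = if (aligned_len > 0) gap_cols / aligned_len else 0,
       tstart = a1$start)
}

#' Merge one read pair into a template-oriented sequence
#'
#' Read 2 is reverse-complemented into template orientation; both mates are
#' aligned to the converted template with \code{\link{align_bisulfite}}. When
#' the aligned template spans overlap by \code{v} columns,
#' \code{round(v * L1 / (L1 + L2))} columns are truncated from the 3' end of
#' read 1's span (round-half-up, so an odd remainder comes off read 1) and the
#' remainder from the 5' end of read 2's span, where L1 and L2 are the aligned
#' column counts. Aligner gaps are then removed and the two parts concatenated.
#' \code{aligned_len} and \code{gap_fraction} are recorded over the truncated
#' alignment columns before gap removal.
#'
#' @param read1,read2 Read sequences with primer prefixes already removed;
#'   \code{read2} in sequencer (reverse-strand) orientation.
#' @param template An \code{\link{amplicon_template}}.
#' @return A merged-read list with \code{sequence}, \code{aligned_len},
#'   \code{gap_fraction}, \code{tstart}, and \code{amplicon}; or
#'   \code{list(rejected = "discordant")} when read 2 aligns entirely 5' of
#'   read 1.
#' @export
merge_pair <- function(read1, read2, template) {
  tmpl <- template$converted_seq
  as_merge_input <- function(a) {
    list(start = a$start, end = a$end, read_aln = a$read_aln,
         tmpl_aln = a$template_aln)
  }
  a1 <- as_merge_input(align_bisulfite(read1, tmpl))
  a2 <- as_merge_input(align_bisulfite(revcomp(read2), tmpl))
  m <- merge_aligned_pair(a1, a2)
  if (is.null(m$rejected)) m$amplicon <- template$name
  m
}

#' Merged-read quality filter
#'
#' Passes a merged read iff its gap-free length is at least 90\% of the
#' template length and its gap fraction is at most 5\%. Length is checked
#' first, so a read failing both is reported as \code{"short"}.
#'
#' @param merged A merged-read list from \code{\link{merge_pair}}.
#' @param template The corresponding \code{\link{amplicon_template}}.
#' @return \code{list(pass = TRUE)} or \code{list(pass = FALSE, reason =
#'   "short"|"gappy")}.
#' @export
quality_filter <- function(merged, template) {
  if (nchar(merged$sequence) < 0.9 * template$length_bp) {
    return(list(pass = FALSE, reason = "short"))
  }
  if (merged$gap_fraction > 0.05) {
    return(list(pass = FALSE, reason = "gappy"))
  }
  list(pass = TRUE)
}

#' Extract, merge and filter read pairs for one amplicon
#'
#' Batch implementation of the first processing pass: pairs whose mates carry
#' the amplicon's forward and reverse nested primers (exact match at read
#' positions 4-33) are selected, the 33-base primer windows are stripped, both
#' mates are aligned to the converted template, proportionally truncated in
#' their overlap, merged, and passed through \code{\link{quality_filter}}.
#'
#' @param reads1,reads2 Character vectors of mate sequences (sequencer
#'   orientation, same length).
#' @param template An \code{\link{amplicon_template}}.
#' @param ids Optional read identifiers (defaults to \code{read000001}, ...).
#' @return A list with \code{merged}, a data.frame with one row per
#'   primer-matched pair (\code{read_id}, \code{status} of
#'   passed/short/gappy/discordant, \code{sequence}, \code{aligned_len},
#'   \code{gap_fraction}, \code{tstart}), and \code{counts}, the conservation
#'   tally (\code{n_input}, \code{n_primer_unmatched}, \code{n_extracted},
#'   \code{n_passed}, \code{n_short}, \code{n_gappy}, \code{n_discordant}).
#' @export
extract_read_pairs <- function(reads1, reads2, template, ids = NULL) {
  stopifnot(length(reads1) == length(reads2))
  n <- length(reads1)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  hit <- match_primer(reads1, template$primer_fwd) &
    match_primer(reads2, template$primer_rev)
  counts <- c(n_input = n, n_primer_unmatched = sum(!hit))
  ids <- ids[hit]
  r1 <- toupper(substr(reads1[hit], 34L, nchar(reads1[hit])))
  r2 <- revcomp(toupper(substr(reads2[hit], 34L, nchar(reads2[hit]))))
  ne <- length(r1)
  counts["n_extracted"] <- ne
  L <- template$length_bp
  tmpl <- template$converted_seq

  if (ne == 0L) {
    merged <- data.frame(read_id = character(0), status = character(0),
                         sequence = character(0), aligned_len = integer(0),
                         gap_fraction = numeric(0), tstart = integer(0))
  } else {
    a1 <- align_batch(r1, tmpl, anchors = rep(0L, ne))
    a2 <- align_batch(r2, tmpl, anchors = L - nchar(r2))
    status <- character(ne)
    sequence <- character(ne)
    aligned_len <- integer(ne)
    gapfrac <- numeric(ne)
    tstart <- rep(NA_integer_, ne)

    both_fast <- a1$fast & a2$fast
    if (any(both_fast)) {
      i <- which(both_fast)
      n1 <- nchar(r1[i]); n2 <- nchar(r2[i])
      e1 <- a1$end[i]; s2 <- a2$start[i]
      v <- pmax(0L, e1 - s2)
      t1 <- round_half_up(v * n1 / (n1 + n2))
      t2 <- v - t1
      sequence[i] <- paste0(substr(r1[i], 1L, n1 - t1), substr(r2[i], t2 + 1L, n2))
      aligned_len[i] <- n1 + n2 - v
      gapfrac[i] <- 0
      tstart[i] <- a1$start[i]
    }
    for (i in which(!both_fast)) {
      g1 <- list(start = a1$start[i], end = a1$end[i],
                 read_aln = if (a1$fast[i]) r1[i] else a1$read_aln[i],
                 tmpl_aln = if (a1$fast[i]) substr(tmpl, a1$start[i] + 1L, a1$end[i])
                            else a1$template_aln[i])
      g2 <- list(start = a2$start[i], end = a2$end[i],
                 read_aln = if (a2$fast[i]) r2[i] else a2$read_aln[i],
                 tmpl_aln = if (a2$fast[i]) substr(tmpl, a2$start[i] + 1L, a2$end[i])
                            else a2$template_aln[i])
      m <- merge_aligned_pair(g1, g2)
      if (!is.null(m$rejected)) {
        status[i] <- "discordant"
        sequence[i] <- NA_character_
      } else {
        sequence[i] <- m$sequence
        aligned_len[i] <- m$aligned_len
        gapfrac[i] <- m$gap_fraction
        tstart[i] <- m$tstart
      }
    }
    undecided <- status == ""
    short <- undecided & nchar(sequence) < 0.9 * L
    status[short] <- "short"
    gappy <- undecided & !short & gapfrac > 0.05
    status[gappy] <- "gappy"
    status[status == ""] <- "passed"
    merged <- data.frame(read_id = ids, status = status, sequence = sequence,
                         aligned_len = aligned_len, gap_fraction = gapfrac,
                         tstart = tstart)
  }
  counts["n_passed"] <- sum(merged$status == "passed")
  counts["n_short"] <- sum(merged$status == "short")
  counts["n_gappy"] <- sum(merged$status == "gappy")
  counts["n_discordant"] <- sum(merged$status == "discordant")
  list(merged = merged, counts = counts, amplicon = template$name)
}

#' Write / read a per-amplicon extract file
#'
#' The extract file holds the merged, filter-passing sequences of one amplicon
#' and sample as TSV with columns \code{read_id}, \code{sequence},
#' \code{aligned_len}, \code{gap_fraction}, \code{tstart} (0-based template
#' offset of the merged span; all other coordinates in exported tables are
#' 1-based).
#'
#' @param extraction Result of \code{\link{extract_read_pairs}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_extract_file <- function(extraction, path) {
  df <- extraction$merged
  df <- df[df$status == "passed",
           c("read_id", "sequence", "aligned_len", "gap_fraction", "tstart")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_extract_file
#' @export
read_extract_file <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
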