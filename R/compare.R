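# Cross-condition comparison of pattern repertoires: exclusive Venn region
# counts, pooled group comparisons at a reporting cutoff, and the overall
# methylation level.

#' Exclusive Venn region counts for 2-5 pattern sets
#'
#' For every nonempty subset S of the conditions, counts the patterns present
#' in all members of S and in none of the remaining conditions, so each
#' pattern in the union is assigned to exactly one region.
#'
#' @param sets Named list of 2-5 character vectors of patterns (equal pattern
#'   lengths).
#' @return Named integer vector over all nonempty condition subsets; names are
#'   condition names joined by \code{"&"}, in subset-size order.
#' @examples
#' venn_counts(list(A = c("01", "11"), B = c("11", "10")))
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 5L) stop("venn_counts needs between 2 and 5 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  sets <- lapply(sets, unique)
  pats <- unique(unlist(sets, use.names = FALSE))
  if (length(pats)) {
    nc <- unique(nchar(pats))
    if (length(nc) > 1L) stop("patterns must share one length across sets")
  }
  member <- vapply(sets, function(s) pats %in% s, logical(length(pats)))
  if (length(pats) == 1L) member <- matrix(member, nrow = 1L)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  subsets <- subsets[order(rowSums(subsets),
                           apply(!as.matrix(subsets), 1L, paste, collapse = "")), ,
                     drop = FALSE]
  out <- integer(nrow(subsets))
  nm <- character(nrow(subsets))
  for (r in seq_len(nrow(subsets))) {
    sel <- as.logical(subsets[r, ])
    nm[r] <- paste(names(sets)[sel], collapse = "&")
    if (length(pats)) {
      exact <- rowSums(member[, sel, drop = FALSE]) == sum(sel) &
        rowSums(member[, !sel, drop = FALSE]) == 0L
      out[r] <- sum(exact)
    }
  }
  names(out) <- nm
  out
}

#' Pooled two-group pattern comparison
#'
#' Each group's pooled pattern set is the union, over its member
#' distributions, of the patterns passing the frequency cutoff within that
#' member (cutoff before pooling). Reports the exclusive and shared counts.
#'
#' @param group_a,group_b Lists of \code{pattern_fit} objects (or named
#'   frequency vectors) from the same amplicon.
#' @param cutoff Minimum estimated frequency (e.g. 0.01).
#' @return List with \code{a_only}, \code{b_only}, \code{shared} (counts),
#'   \code{set_a}, \code{set_b} (pattern vectors), and \code{amplicon}.
#' @export
pooled_comparison <- function(group_a, group_b, cutoff = 0.01) {
  amp_of <- function(x) if (inherits(x, "pattern_fit")) x$amplicon else NA_character_
  amps <- unique(stats::na.omit(c(vapply(group_a, amp_of, character(1)),
                                  vapply(group_b, amp_of, character(1)))))
  if (length(amps) > 1L) {
    stop("integrity error: pooled comparison mixes amplicons: ",
         paste(amps, collapse = ", "))
  }
  pool <- function(group) {
    unique(unlist(lapply(group, function(x) apply_cutoff(x, cutoff)$patterns),
                  use.names = FALSE))
  }
  set_a <- pool(group_a)
  set_b <- pool(group_b)
  shared <- intersect(set_a, set_b)
  list(a_only = length(setdiff(set_a, set_b)),
       b_only = length(setdiff(set_b, set_a)),
       shared = length(shared),
       set_a = set_a, set_b = set_b,
       amplicon = if (length(amps)) amps else NA_character_)
}

#' Cumulative counts over per-amplicon comparisons
#'
#' Sums the exclusive and shared counts of several per-amplicon
#' \code{\link{pooled_comparison}} results, e.g. across the genes of a panel.
#'
#' @param comparisons List of \code{pooled_comparison} results.
#' @return Named integer vector with \code{a_only}, \code{b_only},
#'   \code{shared}.
#' @export
cumulative_comparison <- function(comparisons) {
  c(a_only = sum(vapply(comparisons, `[[`, numeric(1), "a_only")),
    b_only = sum(vapply(comparisons, `[[`, numeric(1), "b_only")),
    shared = sum(vapply(comparisons, `[[`, numeric(1), "shared")))
}

#' Overall methylation level of a distribution
#'
#' Mean over CpGs of the per-CpG combined levels.
#'
#' @param dist A \code{pattern_fit}, \code{pattern_counts}, or named frequency
#'   vector.
#' @return A fraction in \code{[0, 1]}.
#' @export
overall_level <- function(dist) {
  mean(per_cpg_levels(dist))
}

#' Write Venn region counts as TSV
#'
#' @param counts Result of \code{\link{venn_counts}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_venn_counts <- function(counts, path) {
  write.table(data.frame(region = names(counts), count = unname(counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
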