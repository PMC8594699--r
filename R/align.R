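#' Bisulfite-aware pairwise alignment
#'
#' Globally aligns a read to a bisulfite-converted template with free end gaps
#' on the read row, so the read may fall anywhere inside the template without
#' penalty for the template overhang. A read T opposite a template C is scored
#' as a match (+\code{match}), reflecting that an unmethylated, converted
#' cytosine is sequenced as T while the CpG C is retained in the template; all
#' other equalities score +\code{match} and inequalities \code{mismatch}. A gap
#' of length k costs \code{gap_open + k * gap_extend}. Traceback is
#' deterministic: diagonal is preferred over up (read base against gap) over
#' left (gap against template base), and among equal-scoring end columns the
#' rightmost is chosen.
#'
#' @param read,template Non-empty DNA strings; \code{template} is normally the
#'   \code{converted_seq} of an \code{\link{amplicon_template}}.
#' @param match,mismatch Per-column scores (defaults +2 / -3).
#' @param gap_open,gap_extend Positive gap penalties (defaults 5 / 2).
#' @return A list with \code{read_aln} and \code{template_aln} (equal-length
#'   gapped strings over the aligned span), \code{score}, and the 0-based
#'   half-open template span \code{start}, \code{end}.
#' @examples
#' a <- align_bisulfite("TTGA", "TCGATTGA")
#' a$start  # 4
#' @export
align_bisulfite <- function(read, template, match = 2L, mismatch = -3L,
                            gap_open = 5L, gap_extend = 2L) {
  stopifnot(nchar(read) > 0L, nchar(template) > 0L)
  cpp_bis_align(toupper(read), toupper(template), as.integer(match),
                as.integer(mismatch), as.integer(gap_open), as.integer(gap_extend))
}

# Batch alignment with anchored exact-compatibility shortcut (see align.cpp).
align_batch <- function(reads, template, anchors = rep(NA_integer_, length(reads)),
                        match = 2L, mismatch = -3L, gap_open = 5L, gap_extend = 2L) {
  cpp_align_batch(reads, template, as.integer(anchors), as.integer(match),
                  as.integer(mismatch), as.integer(gap_open), as.integer(gap_extend))
}
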