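#' Locate CpG sites in a DNA sequence
#'
#' Returns the 0-based offsets of the C of every CG dinucleotide on the given
#' (top) strand. \code{N} never matches.
#'
#' @param seq A DNA string containing only A/C/G/T/N.
#' @return Integer vector of strictly increasing 0-based offsets (empty for an
#'   empty sequence).
#' @examples
#' scan_cpg_sites("ACGT")  # 1
#' scan_cpg_sites("CGCG")  # 0 2
#' @export
scan_cpg_sites <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return(integer(0))
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters other than A/C/G/T/N")
  }
  # CG cannot overlap CG, so a plain non-overlapping scan is exhaustive
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' In-silico bisulfite conversion of an amplicon template
#'
#' Converts every cytosine outside a CpG context to T (fully converted,
#' unmethylated) while retaining the C of each CpG site, mimicking the top
#' strand of a PCR product from fully methylated CpGs. The result is the
#' alignment template for bisulfite reads.
#'
#' @param genomic_seq DNA string (top strand).
#' @param cpg_positions 0-based offsets of CpG cytosines to retain; defaults to
#'   \code{scan_cpg_sites(genomic_seq)}.
#' @return Converted DNA string of the same length.
#' @examples
#' convert_template("ACAT", integer(0))  # "ATAT"
#' convert_template("ACGT", 1L)          # "ACGT"
#' @export
convert_template <- function(genomic_seq, cpg_positions = scan_cpg_sites(genomic_seq)) {
  stopifnot(is.character(genomic_seq), length(genomic_seq) == 1L)
  genomic_seq <- toupper(genomic_seq)
  chars <- strsplit(genomic_seq, "", fixed = TRUE)[[1L]]
  cpg_positions <- as.integer(cpg_positions)
  if (any(cpg_positions < 0L | cpg_positions >= length(chars))) {
    stop("cpg_positions out of range")
  }
  if (length(cpg_positions) && any(chars[cpg_positions + 1L] != "C")) {
    stop("cpg_positions must index 'C' bases in genomic_seq")
  }
  keep <- logical(length(chars))
  keep[cpg_positions + 1L] <- TRUE
  conv <- chars
  conv[conv == "C" & !keep] <- "T"
  paste(conv, collapse = "")
}

#' Construct an amplicon template
#'
#' Bundles the genomic sequence of one amplicon with its in-silico converted
#' form, CpG (and optional SNP) coordinates, and the nested-primer sequences
#' used for read extraction. Coordinates are held 0-based internally; exported
#' tables and config files use 1-based inclusive coordinates.
#'
#' @param name Amplicon identifier.
#' @param genomic_seq Top-strand DNA (A/C/G/T only; N is rejected so that every
#'   pattern position is certain).
#' @param primer_fwd,primer_rev Nested primer sequences in bisulfite-converted
#'   read space (at least 30 nt).
#' @param cpg_positions Optional 0-based CpG offsets; derived by
#'   \code{\link{scan_cpg_sites}} when omitted, validated when supplied.
#' @param snp_positions Optional 0-based offsets of known SNPs.
#' @return An object of class \code{amplicon_template} with fields
#'   \code{name}, \code{genomic_seq}, \code{converted_seq}, \code{cpg_positions},
#'   \code{snp_positions}, \code{primer_fwd}, \code{primer_rev}, \code{length_bp}.
#' @export
amplicon_template <- function(name, genomic_seq, primer_fwd, primer_rev,
                              cpg_positions = NULL, snp_positions = integer(0)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genomic_seq <- toupper(genomic_seq)
  if (grepl("[^ACGT]", genomic_seq)) {
    stop("configuration error in 'genomic_seq': only A/C/G/T allowed (no N) for amplicon ", name)
  }
  primer_fwd <- toupper(primer_fwd)
  primer_rev <- toupper(primer_rev)
  if (nchar(primer_fwd) < 30L) {
    stop("configuration error in 'primer_fwd': primer shorter than 30 nt for amplicon ", name)
  }
  if (nchar(primer_rev) < 30L) {
    stop("configuration error in 'primer_rev': primer shorter than 30 nt for amplicon ", name)
  }
  auto <- scan_cpg_sites(genomic_seq)
  if (is.null(cpg_positions)) {
    cpg_positions <- auto
  } else {
    cpg_positions <- as.integer(sort(cpg_positions))
    if (!identical(cpg_positions, auto)) {
      stop("configuration error in 'cpg_positions': supplied positions do not match ",
           "CG dinucleotides of the sequence for amplicon ", name)
    }
  }
  snp_positions <- as.integer(sort(snp_positions))
  L <- nchar(genomic_seq)
  if (length(snp_positions) && any(snp_positions < 0L | snp_positions >= L)) {
    stop("configuration error in 'snp_positions': out of range for amplicon ", name)
  }
  obj <- list(name = name,
              genomic_seq = genomic_seq,
              converted_seq = convert_template(genomic_seq, cpg_positions),
              cpg_positions = cpg_positions,
              snp_positions = snp_positions,
              primer_fwd = primer_fwd,
              primer_rev = primer_rev,
              length_bp = L)
  class(obj) <- "amplicon_template"
  obj
}

#' @export
print.amplicon_template <- function(x, ...) {
  cat("Amplicon template '", x$name, "': ", x$length_bp, " bp, ",
      length(x$cpg_positions), " CpG sites", sep = "")
  if (length(x$snp_positions)) cat(", ", length(x$snp_positions), " SNP positions", sep = "")
  cat("\n  CpG positions (1-based): ",
      paste(x$cpg_positions + 1L, collapse = ", "), "\n", sep = "")
  invisible(x)
}
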