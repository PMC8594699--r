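# Panel definitions: amplicon sequences live in a FASTA file, primers and
# optional coordinates in a TOML config with one [[amplicon]] table per
# amplicon.  Coordinates in the config are 1-based inclusive.

# Minimal TOML reader covering the subset used by panel configs:
# [[table]] array headers, string values, and arrays of integers.  No
# general-purpose TOML parser is available in the dependency stack, and the
# panel format needs only this subset.
parse_panel_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  entries <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[\\[\\s*amplicon\\s*\\]\\]$", ln)) {
      if (!is.null(current)) entries[[length(entries) + 1L]] <- current
      current <- list()
    } else if (grepl("^\\[", ln)) {
      stop("configuration error: unsupported table header in panel config: ", ln)
    } else {
      if (is.null(current)) {
        stop("configuration error: key outside an [[amplicon]] table: ", ln)
      }
      kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1L]]
      if (length(kv) != 3L) stop("configuration error: cannot parse line: ", ln)
      key <- kv[2L]
      val <- trimws(kv[3L])
      if (grepl("^\"", val)) {
        current[[key]] <- sub("^\"(.*)\"$", "\\1", val)
      } else if (grepl("^\\[", val)) {
        inner <- sub("^\\[(.*)\\]$", "\\1", val)
        items <- trimws(strsplit(inner, ",", fixed = TRUE)[[1L]])
        items <- items[nzchar(items)]
        current[[key]] <- as.integer(items)
      } else {
        current[[key]] <- as.integer(val)
      }
    }
  }
  if (!is.null(current)) entries[[length(entries) + 1L]] <- current
  entries
}

#' Load an amplicon panel from FASTA + config
#'
#' Reads amplicon genomic sequences from a FASTA file and per-amplicon primers
#' and optional CpG/SNP coordinates from a TOML config containing one
#' \code{[[amplicon]]} table per amplicon with keys \code{name},
#' \code{primer_fwd}, \code{primer_rev} and optional \code{cpg_positions},
#' \code{snp_positions} (1-based inclusive). CpG positions are derived from the
#' sequence when absent and validated against it when supplied.
#'
#' @param template_fasta Path to the FASTA file of amplicon genomic sequences.
#' @param panel_config Path to the TOML panel config.
#' @return Named list of \code{\link{amplicon_template}} objects.
#' @export
load_panel <- function(template_fasta, panel_config) {
  seqs <- Biostrings::readDNAStringSet(template_fasta)
  seq_map <- as.character(seqs)
  names(seq_map) <- sub("\\s.*$", "", names(seqs))
  entries <- parse_panel_toml(panel_config)
  if (!length(entries)) stop("configuration error: no [[amplicon]] entries in ", panel_config)
  templates <- lapply(entries, function(e) {
    for (req in c("name", "primer_fwd", "primer_rev")) {
      if (is.null(e[[req]])) stop("configuration error: missing key '", req, "' in panel config")
    }
    if (!e$name %in% names(seq_map)) {
      stop("configuration error in 'name': FASTA record '", e$name, "' not found in ",
           template_fasta)
    }
    cpg <- if (is.null(e$cpg_positions)) NULL else as.integer(e$cpg_positions) - 1L
    snp <- if (is.null(e$snp_positions)) integer(0) else as.integer(e$snp_positions) - 1L
    amplicon_template(name = e$name,
                      genomic_seq = seq_map[[e$name]],
                      primer_fwd = e$primer_fwd,
                      primer_rev = e$primer_rev,
                      cpg_positions = cpg,
                      snp_positions = snp)
  })
  names(templates) <- vapply(templates, `[[`, character(1), "name")
  templates
}

#' Write an amplicon panel to FASTA + config
#'
#' Inverse of \code{\link{load_panel}}: writes the genomic sequences to FASTA
#' and the primers plus 1-based CpG/SNP coordinates to a TOML config, such that
#' reloading reproduces the templates field-by-field.
#'
#' @param templates List of \code{\link{amplicon_template}} objects.
#' @param template_fasta,panel_config Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_panel <- function(templates, template_fasta, panel_config) {
  seqs <- Biostrings::DNAStringSet(vapply(templates, `[[`, character(1), "genomic_seq"))
  names(seqs) <- vapply(templates, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, template_fasta)
  out <- c("# amplicon panel config; coordinates are 1-based inclusive")
  for (tp in templates) {
    out <- c(out,
             "",
             "[[amplicon]]",
             sprintf('name = "%s"', tp$name),
             sprintf('primer_fwd = "%s"', tp$primer_fwd),
             sprintf('primer_rev = "%s"', tp$primer_rev),
             sprintf("cpg_positions = [%s]", paste(tp$cpg_positions + 1L, collapse = ", ")))
    if (length(tp$snp_positions)) {
      out <- c(out, sprintf("snp_positions = [%s]", paste(tp$snp_positions + 1L, collapse = ", ")))
    }
  }
  writeLines(out, panel_config)
  invisible(list(template_fasta = template_fasta, panel_config = panel_config))
}
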