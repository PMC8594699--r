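# Programmatic fixtures: synthetic amplicon templates with exact CpG counts,
# panels mirroring the 551/401/405 bp x 10/10/15 CpG geometry, and small
# sample sheets.  All fixtures are built in code at test time.

make_seq <- function(len, n_cpgs, seed) {
  set.seed(seed)
  repeat {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    repeat {
      str <- paste(s, collapse = "")
      hits <- scan_cpg_sites(str)
      if (!length(hits)) break
      s[hits + 2L] <- "A"
    }
    pos <- sort(sample(seq(40L, len - 40L), n_cpgs))
    if (any(diff(pos) < 3L)) next
    s[pos] <- "C"
    s[pos + 1L] <- "G"
    str <- paste(s, collapse = "")
    if (length(scan_cpg_sites(str)) == n_cpgs) return(str)
  }
}

# Template whose primers are the first/last 33 converted bases (CpG-free by
# construction of make_seq, which keeps CpGs 40 bp from the ends).
make_template <- function(len, n_cpgs, seed, name = "amp1") {
  gseq <- make_seq(len, n_cpgs, seed)
  conv <- convert_template(gseq)
  amplicon_template(name, gseq,
                    primer_fwd = substr(conv, 1L, 33L),
                    primer_rev = epiamplicon:::revcomp(substr(conv, len - 32L, len)))
}

# The three-amplicon panel geometry used throughout: 551/401/405 bp with
# 10/10/15 CpGs.
make_panel <- function(seed = 100L) {
  list(dynA = make_template(551L, 10L, seed + 1L, "dynA"),
       pkcB = make_template(401L, 10L, seed + 2L, "pkcB"),
       nadC = make_template(405L, 15L, seed + 3L, "nadC"))
}

random_pattern_counts <- function(n_cpgs, k, n, seed) {
  mix <- generate_epiallele_mixture(n_cpgs, k, concentration = 1.5, seed = seed)
  pats <- simulate_observed_patterns(mix, error_model(), n, seed = seed + 1L)
  tabulate_patterns(pats)
}
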