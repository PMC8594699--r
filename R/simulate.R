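# Synthetic epiallele mixtures and paired bisulfite amplicon reads with known
# truth, used for end-to-end validation of the pipeline.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Bisulfite/sequencing error model
#'
#' Collects the error rates of the observation process: \code{f_nonconv} is the
#' probability that an unmethylated CpG cytosine escapes bisulfite conversion
#' (read as C), \code{g_overconv} the probability that a methylated CpG
#' cytosine is converted anyway (read as T), \code{m_subst} the per-base
#' sequencing substitution rate, \code{r_indel} the per-base sequencing indel
#' rate, and \code{nonCpG_fail} the probability that a cytosine outside a CpG
#' context escapes conversion.
#'
#' All rates default to 0 (an error-free instrument).
#'
#' @param f_nonconv,g_overconv,m_subst,r_indel,nonCpG_fail Probabilities in
#'   \code{[0, 1]}.
#' @return An object of class \code{error_model}.
#' @export
error_model <- function(f_nonconv = 0, g_overconv = 0, m_subst = 0,
                        r_indel = 0, nonCpG_fail = 0) {
  vals <- c(f_nonconv = f_nonconv, g_overconv = g_overconv, m_subst = m_subst,
            r_indel = r_indel, nonCpG_fail = nonCpG_fail)
  if (any(vals < 0 | vals > 1)) stop("error rates must lie in [0, 1]")
  structure(as.list(vals), class = "error_model")
}

#' Default error model used for simulation studies
#'
#' Plausible residual rates after double bisulfite treatment and Illumina
#' sequencing: non-conversion and over-conversion 0.5%, substitutions 0.3%,
#' indels 0.05%, non-CpG conversion failure 0.2%.
#'
#' @return An \code{\link{error_model}}.
#' @export
default_error_model <- function() {
  error_model(f_nonconv = 0.005, g_overconv = 0.005, m_subst = 0.003,
              r_indel = 0.0005, nonCpG_fail = 0.002)
}

#' @export
print.error_model <- function(x, ...) {
  cat("Error model: f_nonconv =", x$f_nonconv, ", g_overconv =", x$g_overconv,
      ", m_subst =", x$m_subst, ", r_indel =", x$r_indel,
      ", nonCpG_fail =", x$nonCpG_fail, "\n")
  invisible(x)
}

#' Construct an epiallele mixture
#'
#' @param patterns Character vector of distinct binary pattern strings, all of
#'   the same length.
#' @param frequencies Positive fractions summing to 1.
#' @return An object of class \code{epiallele_mixture} with fields
#'   \code{n_cpgs}, \code{patterns}, \code{frequencies}.
#' @export
epiallele_mixture <- function(patterns, frequencies) {
  stopifnot(length(patterns) == length(frequencies), length(patterns) >= 1L)
  if (anyDuplicated(patterns)) stop("mixture patterns must be pairwise distinct")
  nc <- unique(nchar(patterns))
  if (length(nc) != 1L) stop("mixture patterns must share one length")
  if (any(grepl("[^01]", patterns))) stop("patterns must be binary strings")
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0)) stop("mixture frequencies must be positive")
  if (abs(sum(frequencies) - 1) > 1e-9) stop("mixture frequencies must sum to 1")
  ord <- order(-frequencies, patterns)
  structure(list(n_cpgs = nc, patterns = patterns[ord], frequencies = frequencies[ord]),
            class = "epiallele_mixture")
}

#' @export
print.epiallele_mixture <- function(x, ...) {
  cat("Epiallele mixture over", x$n_cpgs, "CpGs,", length(x$patterns), "components\n")
  print(data.frame(pattern = x$patterns, frequency = signif(x$frequencies, 4)))
  invisible(x)
}

int_to_pattern <- function(ints, n_cpgs) {
  vapply(ints, function(v) {
    bits <- integer(n_cpgs)
    for (j in n_cpgs:1) { bits[j] <- v %% 2L; v <- v %/% 2L }
    paste(bits, collapse = "")
  }, character(1))
}

#' Generate a random epiallele mixture
#'
#' Draws \code{k} distinct patterns uniformly without replacement from the
#' \code{2^n_cpgs} possible patterns and gives them frequencies from a
#' symmetric Dirichlet distribution, sorted descending. A small \code{k} with a
#' skewed Dirichlet mirrors brain amplicon data, where most molecules carry one
#' of roughly a dozen dominant epiallele patterns.
#'
#' @param n_cpgs Number of CpG sites in the amplicon.
#' @param k Number of mixture components (\code{1 <= k <= 2^n_cpgs}).
#' @param concentration Dirichlet concentration (> 0); values near 1 give
#'   strongly skewed frequencies.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return An \code{\link{epiallele_mixture}}.
#' @export
generate_epiallele_mixture <- function(n_cpgs, k, concentration = 1, seed) {
  stopifnot(n_cpgs >= 1L, concentration > 0)
  if (k < 1 || (n_cpgs < 31 && k > 2^n_cpgs)) {
    stop("k must satisfy 1 <= k <= 2^n_cpgs")
  }
  with_seed(seed, {
    if (n_cpgs <= 25) {
      ints <- sample.int(2^n_cpgs, k) - 1
      pats <- int_to_pattern(ints, n_cpgs)
    } else {
      pats <- character(0)
      while (length(pats) < k) {
        cand <- paste(sample(c("0", "1"), n_cpgs, replace = TRUE), collapse = "")
        if (!cand %in% pats) pats <- c(pats, cand)
      }
    }
    w <- stats::rgamma(k, shape = concentration)
    # guard against numerically zero gamma draws at tiny concentrations
    w <- pmax(w, 1e-12)
    epiallele_mixture(pats, w / sum(w))
  })
}

# Multinomial component draw for n molecules; assumes the RNG state is set.
draw_pattern_indices <- function(mixture, n) {
  sample.int(length(mixture$patterns), n, replace = TRUE, prob = mixture$frequencies)
}

#' Simulate observed methylation patterns through the error channel
#'
#' Pattern-level companion to \code{\link{simulate_reads}}: molecules are drawn
#' from the mixture and each CpG state is passed through the conversion error
#' (non-conversion \code{f_nonconv}, over-conversion \code{g_overconv}) and
#' then through a C/T-flipping sequencing substitution with rate
#' \code{m_subst}. Useful for calibration studies of the frequency estimator
#' without read-level simulation.
#'
#' @param mixture An \code{\link{epiallele_mixture}}.
#' @param error_model An \code{\link{error_model}} (indel and non-CpG rates are
#'   irrelevant at pattern level and ignored).
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @return Character vector of \code{n} observed pattern strings.
#' @export
simulate_observed_patterns <- function(mixture, error_model, n, seed) {
  stopifnot(inherits(mixture, "epiallele_mixture"), inherits(error_model, "error_model"),
            n >= 1)
  J <- mixture$n_cpgs
  with_seed(seed, {
    idx <- draw_pattern_indices(mixture, n)
    B <- pattern_matrix(mixture$patterns)[idx, , drop = FALSE]
    # conversion stage: methylated survives as C unless over-converted;
    # unmethylated reads as T unless conversion fails
    U <- matrix(runif(n * J), n, J)
    obs <- ifelse(B == 1L, ifelse(U < error_model$g_overconv, 0L, 1L),
                  ifelse(U < error_model$f_nonconv, 1L, 0L))
    # sequencing stage: a C/T substitution flips the call
    if (error_model$m_subst > 0) {
      V <- matrix(runif(n * J), n, J)
      obs <- ifelse(V < error_model$m_subst, 1L - obs, obs)
    }
    apply(obs, 1L, paste, collapse = "")
  })
}

primer_read_prefix <- function(primer) {
  lp <- nchar(primer)
  last30 <- substr(primer, lp - 29L, lp)
  pad <- if (lp >= 33L) substr(primer, lp - 32L, lp - 30L) else "TCA"
  paste0(pad, last30)
}

#' Simulate paired-end amplicon bisulfite reads
#'
#' For each molecule a pattern is drawn from the mixture; the molecule sequence
#' is built from the genomic template by converting cytosines according to the
#' pattern and the error model (CpG C kept with probability
#' \code{1 - g_overconv} when methylated, with probability \code{f_nonconv}
#' when unmethylated; non-CpG C kept with probability \code{nonCpG_fail});
#' sequencing substitutions and indels are then applied. Read 1 covers the
#' 5' end of the molecule and read 2 the 3' end in reverse complement, each
#' prefixed by its nested primer in read orientation (3 pad bases followed by
#' the primer's last 30 nt, so the exact-primer window sits at read positions
#' 4-33). Qualities are constant 'I'; output is byte-identical for identical
#' arguments.
#'
#' @param template An \code{\link{amplicon_template}}.
#' @param mixture An \code{\link{epiallele_mixture}} over the template's CpGs.
#' @param error_model An \code{\link{error_model}}.
#' @param n_pairs Number of read pairs (> 0).
#' @param read_len Read length in bases (<= template length).
#' @param seed Integer seed.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix; defaults to the template name.
#' @param gzip Write gzip-compressed FASTQ.
#' @return List with paths \code{fastq_r1}, \code{fastq_r2}, \code{truth}.
#' @export
simulate_reads <- function(template, mixture, error_model, n_pairs, read_len,
                           seed, dir = tempdir(), prefix = template$name,
                           gzip = FALSE) {
  stopifnot(inherits(template, "amplicon_template"),
            inherits(mixture, "epiallele_mixture"),
            inherits(error_model, "error_model"))
  if (n_pairs <= 0) stop("n_pairs must be positive")
  if (mixture$n_cpgs != length(template$cpg_positions)) {
    stop("mixture n_cpgs does not match the template's CpG count")
  }
  if (read_len > template$length_bp) stop("read_len must not exceed template length")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  p1 <- file.path(dir, paste0(prefix, "_R1", ext))
  p2 <- file.path(dir, paste0(prefix, "_R2", ext))
  pt <- file.path(dir, paste0(prefix, "_truth.tsv"))

  L <- template$length_bp
  J <- mixture$n_cpgs
  cpg1 <- template$cpg_positions + 1L
  conv_raw <- charToRaw(template$converted_seq)
  genomic <- strsplit(template$genomic_seq, "", fixed = TRUE)[[1L]]
  noncpg_c <- setdiff(which(genomic == "C"), cpg1)
  rawC <- charToRaw("C"); rawT <- charToRaw("T")
  bases <- c("A", "C", "G", "T")

  mols <- with_seed(seed, {
    idx <- draw_pattern_indices(mixture, n_pairs)
    B <- pattern_matrix(mixture$patterns)[idx, , drop = FALSE]
    U <- matrix(runif(n_pairs * J), n_pairs, J)
    cpg_is_c <- (B == 1L & U >= error_model$g_overconv) |
      (B == 0L & U < error_model$f_nonconv)
    # sparse non-CpG conversion failures
    esc <- vector("list", n_pairs)
    if (error_model$nonCpG_fail > 0 && length(noncpg_c)) {
      tot <- n_pairs * length(noncpg_c)
      n_esc <- rbinom(1L, tot, error_model$nonCpG_fail)
      if (n_esc > 0) {
        pos <- sort(sample.int(tot, n_esc))
        mol_of <- (pos - 1L) %/% length(noncpg_c) + 1L
        site_of <- noncpg_c[(pos - 1L) %% length(noncpg_c) + 1L]
        esc <- split(site_of, factor(mol_of, levels = seq_len(n_pairs)))
      }
    }
    # sparse substitutions
    subs <- vector("list", n_pairs)
    if (error_model$m_subst > 0) {
      n_sub <- rbinom(1L, n_pairs * L, error_model$m_subst)
      if (n_sub > 0) {
        pos <- sort(sample.int(n_pairs * L, n_sub))
        mol_of <- (pos - 1L) %/% L + 1L
        site_of <- (pos - 1L) %% L + 1L
        shift <- sample.int(3L, n_sub, replace = TRUE)
        subs <- split(data.frame(site = site_of, shift = shift),
                      factor(mol_of, levels = seq_len(n_pairs)))
      }
    }
    # sparse indels: half deletions, half insertions
    dels <- vector("list", n_pairs); inss <- vector("list", n_pairs)
    if (error_model$r_indel > 0) {
      n_del <- rbinom(1L, n_pairs * L, error_model$r_indel / 2)
      if (n_del > 0) {
        pos <- sort(sample.int(n_pairs * L, n_del))
        dels <- split((pos - 1L) %% L + 1L,
                      factor((pos - 1L) %/% L + 1L, levels = seq_len(n_pairs)))
      }
      n_ins <- rbinom(1L, n_pairs * L, error_model$r_indel / 2)
      if (n_ins > 0) {
        pos <- sort(sample.int(n_pairs * L, n_ins))
        ins_base <- sample(bases, n_ins, replace = TRUE)
        inss <- split(data.frame(site = (pos - 1L) %% L + 1L, base = ins_base),
                      factor((pos - 1L) %/% L + 1L, levels = seq_len(n_pairs)))
      }
    }
    list(idx = idx, cpg_is_c = cpg_is_c, esc = esc, subs = subs,
         dels = dels, inss = inss)
  })

  seqs <- character(n_pairs)
  raw_bases <- vapply(bases, charToRaw, raw(1))
  for (i in seq_len(n_pairs)) {
    r <- conv_raw
    cc <- mols$cpg_is_c[i, ]
    r[cpg1[cc]] <- rawC
    r[cpg1[!cc]] <- rawT
    e <- mols$esc[[i]]
    if (length(e)) r[e] <- rawC
    s <- mols$subs[[i]]
    if (!is.null(s) && nrow(s)) {
      for (q in seq_len(nrow(s))) {
        cur <- which(raw_bases == r[s$site[q]])
        r[s$site[q]] <- raw_bases[(cur - 1L + s$shift[q]) %% 4L + 1L]
      }
    }
    d <- mols$dels[[i]]; ins <- mols$inss[[i]]
    if (length(d) || (!is.null(ins) && nrow(ins))) {
      chars <- strsplit(rawToChar(r), "", fixed = TRUE)[[1L]]
      if (!is.null(ins) && nrow(ins)) {
        # insert before the given site, applied right-to-left
        for (q in rev(seq_len(nrow(ins)))) {
          chars <- append(chars, ins$base[q], after = ins$site[q] - 1L)
        }
      }
      if (length(d)) {
        # deletion sites refer to original coordinates; adjust for insertions
        # by deleting matching original bases from the right
        keep <- rep(TRUE, length(chars))
        off <- if (!is.null(ins) && nrow(ins)) {
          vapply(d, function(p) sum(ins$site <= p), integer(1))
        } else rep(0L, length(d))
        keep[unique(pmin(d + off, length(chars)))] <- FALSE
        chars <- chars[keep]
      }
      seqs[i] <- paste(chars, collapse = "")
    } else {
      seqs[i] <- rawToChar(r)
    }
  }

  pre1 <- primer_read_prefix(template$primer_fwd)
  pre2 <- primer_read_prefix(template$primer_rev)
  lens <- nchar(seqs)
  r1 <- paste0(pre1, substr(seqs, 1L, read_len))
  r2 <- paste0(pre2, revcomp(substr(seqs, pmax(1L, lens - read_len + 1L), lens)))
  ids <- sprintf("%s:mol%06d", template$name, seq_len(n_pairs))

  write_fastq(p1, ids, r1)
  write_fastq(p2, ids, r2)

  tally <- tabulate(mols$idx, nbins = length(mixture$patterns))
  truth <- data.frame(pattern = mixture$patterns,
                      true_frequency = mixture$frequencies,
                      molecules = tally)
  write.table(truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fastq_r1 = p1, fastq_r2 = p2, truth = pt)
}

write_fastq <- function(path, ids, seqs) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  qual <- strrep("I", nchar(seqs))
  rec <- paste0("@", ids, "\n", seqs, "\n+\n", qual)
  writeLines(rec, con, sep = "\n")
}

read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(ids = sub("\\s.*$", "", names(ss)), seqs = as.character(ss))
}
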