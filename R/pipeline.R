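# End-to-end orchestration: panel + sample sheet in, tables, figures and a
# machine-readable manifest out.

#' Pipeline run configuration
#'
#' @param panel_fasta,panel_config Paths to the amplicon panel (see
#'   \code{\link{load_panel}}).
#' @param sample_sheet Path to a TSV with columns \code{sample},
#'   \code{condition}, \code{fastq_r1}, \code{fastq_r2}.
#' @param out_dir Output directory.
#' @param error_model \code{\link{error_model}} used by the frequency
#'   estimator.
#' @param cutoffs Reporting frequency cutoffs, each in \code{[0, 1)}.
#' @param support_cut Spurious-pattern elimination threshold (default
#'   \code{10 / n_reads} per table).
#' @param seed Integer seed recorded in the manifest.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(panel_fasta, panel_config, sample_sheet, out_dir,
                       error_model = default_error_model(),
                       cutoffs = c(0.01, 0.05), support_cut = NULL, seed = 1L) {
  for (p in c(panel_fasta, panel_config, sample_sheet)) {
    if (!file.exists(p)) stop("configuration error: file not found: ", p)
  }
  if (any(cutoffs < 0 | cutoffs >= 1)) {
    stop("configuration error in 'cutoffs': each cutoff must lie in [0, 1)")
  }
  samples <- read.delim(sample_sheet, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "fastq_r1", "fastq_r2")
  if (!all(need %in% names(samples))) {
    stop("configuration error in 'sample_sheet': need columns ",
         paste(need, collapse = ", "))
  }
  base <- dirname(normalizePath(sample_sheet))
  for (col in c("fastq_r1", "fastq_r2")) {
    rel <- !file.exists(samples[[col]])
    samples[[col]][rel] <- file.path(base, samples[[col]][rel])
    if (any(!file.exists(samples[[col]]))) {
      stop("configuration error in '", col, "': FASTQ not found: ",
           paste(samples[[col]][!file.exists(samples[[col]])], collapse = ", "))
    }
  }
  structure(list(panel_fasta = panel_fasta, panel_config = panel_config,
                 samples = samples, out_dir = out_dir, error_model = error_model,
                 cutoffs = sort(cutoffs), support_cut = support_cut,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pattern-analysis pipeline
#'
#' For every sample and amplicon: select read pairs by exact nested-primer
#' match, merge and filter them (\code{\link{extract_read_pairs}}), call
#' per-read methylation patterns (\code{\link{call_patterns}}), tabulate
#' unique patterns, estimate the denoised pattern distribution
#' (\code{\link{fit_pattern_mixture}}), and export per-CpG levels. Conditions
#' are then compared per amplicon with exclusive Venn counts at every
#' reporting cutoff. All tables are TSV; a JSON manifest records the seed,
#' package version and the read tally of every filter stage, and is identical
#' across re-runs on identical inputs.
#'
#' @param config A \code{\link{run_config}}.
#' @param figures Render figures via \code{\link{render_reports}}.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  for (d in c("extract", "counts", "dist", "levels", "compare")) {
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)
  }
  panel <- withCallingHandlers(
    load_panel(config$panel_fasta, config$panel_config),
    error = function(e) stop("stage reference_prep failed: ", conditionMessage(e),
                             call. = FALSE))
  manifest <- list(package = "epiamplicon",
                   version = as.character(packageVersion("epiamplicon")),
                   seed = config$seed,
                   cutoffs = config$cutoffs,
                   error_model = unclass(config$error_model),
                   amplicons = lapply(panel, function(tp) {
                     list(length_bp = tp$length_bp, n_cpgs = length(tp$cpg_positions))
                   }),
                   samples = list())
  fits <- list()
  for (si in seq_len(nrow(config$samples))) {
    smp <- config$samples[si, ]
    fq1 <- read_fastq(smp$fastq_r1)
    fq2 <- read_fastq(smp$fastq_r2)
    if (length(fq1$seqs) != length(fq2$seqs)) {
      stop("stage read_extraction failed: mate counts differ for sample ", smp$sample)
    }
    sample_entry <- list(condition = smp$condition, n_read_pairs = length(fq1$seqs),
                         amplicons = list())
    for (amp in names(panel)) {
      tp <- panel[[amp]]
      ex <- withCallingHandlers(
        extract_read_pairs(fq1$seqs, fq2$seqs, tp, ids = fq1$ids),
        error = function(e) stop("stage read_extraction failed for sample ",
                                 smp$sample, ", amplicon ", amp, ": ",
                                 conditionMessage(e), call. = FALSE))
      stem <- paste0(smp$sample, ".", amp)
      write_extract_file(ex, file.path(out, "extract", paste0(stem, ".extract.tsv")))
      passed <- ex$merged[ex$merged$status == "passed", , drop = FALSE]
      calls <- withCallingHandlers(
        call_patterns(passed$sequence, tp, tstart = passed$tstart),
        error = function(e) stop("stage pattern_calling failed for sample ",
                                 smp$sample, ", amplicon ", amp, ": ",
                                 conditionMessage(e), call. = FALSE))
      tab <- tabulate_patterns(calls$pattern, amplicon = amp, sample = smp$sample,
                               snp_bases = calls$snp_bases)
      write_pattern_counts(tab, file.path(out, "counts", paste0(stem, ".counts.tsv")))
      if (!is.null(tab$snp_counts)) {
        write.table(cbind(amplicon = amp, sample = smp$sample, tab$snp_counts),
                    file.path(out, "counts", paste0(stem, ".snp.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      entry <- as.list(ex$counts)
      entry$n_called <- tab$n_called
      entry$n_ambiguous <- tab$n_ambiguous
      if (tab$n_called > 0L) {
        fit <- withCallingHandlers(
          fit_pattern_mixture(tab, config$error_model,
                              support_cut = config$support_cut),
          error = function(e) stop("stage frequency_estimation failed for sample ",
                                   smp$sample, ", amplicon ", amp, ": ",
                                   conditionMessage(e), call. = FALSE))
        fits[[amp]][[smp$sample]] <- fit
        write_distribution(fit, file.path(out, "dist", paste0(stem, ".dist.tsv")))
        lv <- per_cpg_levels(fit)
        write.table(data.frame(amplicon = amp, sample = smp$sample,
                               cpg_index = seq_along(lv),
                               cpg_pos_1based = tp$cpg_positions + 1L,
                               level = lv),
                    file.path(out, "levels", paste0(stem, ".levels.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        entry$n_patterns_retained <- length(fit$freqs)
        entry$n_patterns_eliminated <- length(fit$eliminated)
        entry$em_iterations <- fit$n_iter
        entry$log_likelihood <- fit$logLik
        entry$overall_level <- overall_level(fit)
      }
      sample_entry$amplicons[[amp]] <- entry
    }
    manifest$samples[[smp$sample]] <- sample_entry
  }
  # per-amplicon condition comparison at each cutoff (up to 5 conditions)
  for (amp in names(fits)) {
    by_cond <- split(fits[[amp]], config$samples$condition[
      match(names(fits[[amp]]), config$samples$sample)])
    if (length(by_cond) >= 2L && length(by_cond) <= 5L) {
      for (cut in config$cutoffs) {
        sets <- lapply(by_cond, function(flist) {
          unique(unlist(lapply(flist, function(f) apply_cutoff(f, cut)$patterns),
                        use.names = FALSE))
        })
        vc <- venn_counts(sets)
        write_venn_counts(vc, file.path(out, "compare",
                                        sprintf("venn.%s.cut%g.tsv", amp, 100 * cut)))
      }
    }
  }
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (figures) render_reports(out)
  invisible(manifest)
}
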