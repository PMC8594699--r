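test_that("pattern calling scores C as 1, T as 0 and everything else ambiguous", {
  tp <- make_template(200L, 5L, seed = 61L)
  conv <- tp$converted_seq
  p1 <- tp$cpg_positions + 1L

  all_c <- conv  # converted template keeps C exactly at CpGs
  expect_identical(call_pattern(all_c, tp)$pattern, "11111")

  all_t <- chartr("C", "T", conv)
  expect_identical(call_pattern(all_t, tp)$pattern, "00000")

  g_at_cpg <- conv
  substr(g_at_cpg, p1[3L], p1[3L]) <- "G"
  res <- call_pattern(g_at_cpg, tp)
  expect_true(res$ambiguous)
  expect_identical(res$pattern, NA_character_)

  # a read not covering the last CpG is ambiguous as a whole
  partial <- substr(conv, 1L, p1[5L] - 1L)
  expect_true(call_pattern(partial, tp)$ambiguous)
})

test_that("indel-shifted reads are rescued by re-alignment", {
  tp <- make_template(200L, 5L, seed = 62L)
  conv <- tp$converted_seq
  # delete one base well before the first CpG: positional shift, same pattern
  del <- paste0(substr(conv, 1L, 10L), substr(conv, 12L, 200L))
  expect_identical(call_pattern(del, tp)$pattern, "11111")
  # insertion likewise
  ins <- paste0(substr(conv, 1L, 10L), "A", substr(conv, 11L, 200L))
  expect_identical(call_pattern(ins, tp)$pattern, "11111")
})

test_that("SNP columns are recorded verbatim and do not affect the pattern", {
  gseq <- make_seq(200L, 4L, seed = 63L)
  conv0 <- convert_template(gseq)
  snp_pos <- 120L  # 0-based; pick a template position that is A/G/T
  while (substr(gseq, snp_pos + 1L, snp_pos + 1L) == "C" ||
         (snp_pos %in% (scan_cpg_sites(gseq) + 1L))) snp_pos <- snp_pos + 1L
  tp <- amplicon_template("s", gseq, substr(conv0, 1L, 33L),
                          epiamplicon:::revcomp(substr(conv0, 168L, 200L)),
                          snp_positions = snp_pos)
  read <- tp$converted_seq
  substr(read, snp_pos + 1L, snp_pos + 1L) <- "G"
  res <- call_pattern(read, tp)
  expect_identical(res$snp_bases, "G")
  expect_identical(res$pattern, strrep("1", 4L))
})

test_that("tabulation counts unique patterns with deterministic ordering", {
  tab <- tabulate_patterns(c("10", "10", "10", "01"))
  expect_identical(unname(tab$counts[c("10", "01")]), c(3L, 1L))
  expect_identical(names(tab$counts), c("10", "01"))
  expect_identical(tab$n_called, 4L)

  empty <- tabulate_patterns(character(0))
  expect_identical(empty$n_called, 0L)
  expect_length(empty$counts, 0L)

  expect_error(tabulate_patterns(c("10", "010")), "integrity")

  # ties broken by pattern string ascending
  tie <- tabulate_patterns(c("11", "00", "11", "00", "01"))
  expect_identical(names(tie$counts), c("00", "11", "01"))

  withna <- tabulate_patterns(c("10", NA, "10", NA, NA))
  expect_identical(withna$n_called, 2L)
  expect_identical(withna$n_ambiguous, 3L)
})

test_that("batch calling agrees with single-read calling and conserves reads", {
  tp <- make_template(250L, 6L, seed = 64L)
  mix <- generate_epiallele_mixture(6L, 4L, seed = 34L)
  em <- error_model(f_nonconv = 0.02, g_overconv = 0.02, m_subst = 0.01,
                    r_indel = 0.01)
  p <- simulate_reads(tp, mix, em, 120L, read_len = 250L, seed = 17L,
                      dir = tempfile())
  fq1 <- epiamplicon:::read_fastq(p$fastq_r1)
  fq2 <- epiamplicon:::read_fastq(p$fastq_r2)
  ex <- extract_read_pairs(fq1$seqs, fq2$seqs, tp)
  passed <- ex$merged[ex$merged$status == "passed", ]
  calls <- call_patterns(passed$sequence, tp, tstart = passed$tstart)
  expect_identical(calls$n_called + calls$n_ambiguous, nrow(passed))
  single <- vapply(passed$sequence, function(s) call_pattern(s, tp)$pattern,
                   character(1), USE.NAMES = FALSE)
  expect_identical(calls$pattern, single)
})

test_that("per-CpG levels equal the brute-force weighted column sums", {
  expect_identical(per_cpg_levels(c("111" = 1.0)), c(1, 1, 1))
  expect_identical(per_cpg_levels(c("10" = 0.5, "01" = 0.5)), c(0.5, 0.5))

  set.seed(71L)
  pats <- unique(replicate(20L, paste(sample(0:1, 8L, TRUE), collapse = "")))
  w <- runif(length(pats)); w <- w / sum(w)
  names(w) <- pats
  brute <- vapply(1:8, function(j) {
    sum(w * as.integer(substr(pats, j, j)))
  }, numeric(1))
  expect_equal(per_cpg_levels(w), brute, tolerance = 1e-12)

  # invariance under permutation of the call stream
  calls <- sample(rep(pats, times = sample(1:5, length(pats), TRUE)))
  t1 <- tabulate_patterns(calls)
  t2 <- tabulate_patterns(rev(calls))
  expect_identical(per_cpg_levels(t1), per_cpg_levels(t2))

  expect_error(per_cpg_levels(numeric(0)), "nonempty")
})

test_that("per-CpG level of a non-conversion-only simulation is near epsilon", {
  tp <- make_template(250L, 6L, seed = 65L)
  eps <- 0.05
  mix <- epiallele_mixture(strrep("0", 6L), 1)
  p <- simulate_reads(tp, mix, error_model(f_nonconv = eps), 1500L,
                      read_len = 250L, seed = 18L, dir = tempfile())
  fq1 <- epiamplicon:::read_fastq(p$fastq_r1)
  fq2 <- epiamplicon:::read_fastq(p$fastq_r2)
  ex <- extract_read_pairs(fq1$seqs, fq2$seqs, tp)
  calls <- call_patterns(ex$merged$sequence, tp, tstart = ex$merged$tstart)
  lv <- per_cpg_levels(tabulate_patterns(calls$pattern))
  se <- sqrt(eps * (1 - eps) / 1500L)
  expect_true(all(abs(lv - eps) <= 3 * se))
})
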