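test_that("primer matching is exact over read positions 4-33", {
  primer <- paste(rep(c("A", "C", "T", "G"), length.out = 33L), collapse = "")
  last30 <- substr(primer, 4L, 33L)
  read <- paste0("TTT", last30, strrep("A", 50L))
  expect_true(match_primer(read, primer))

  bad <- read
  substr(bad, 10L, 10L) <- if (substr(bad, 10L, 10L) == "A") "C" else "A"
  expect_false(match_primer(bad, primer))

  expect_false(match_primer(strrep("A", 20L), primer))
  expect_true(match_primer(tolower(read), primer))
  expect_error(match_primer(read, strrep("A", 29L)))
})

test_that("overlap truncation is proportional with round-half-up", {
  tp <- make_template(100L, 2L, seed = 51L)
  tmpl <- tp$converted_seq
  # spans [0,60) and [40,100): v = 20, L1 = L2 = 60 -> 10 columns each side
  r1 <- substr(tmpl, 1L, 60L)
  r2 <- epiamplicon:::revcomp(substr(tmpl, 41L, 100L))
  m <- merge_pair(r1, r2, tp)
  expect_identical(m$sequence, tmpl)
  expect_identical(m$aligned_len, 100L)
  expect_identical(m$gap_fraction, 0)

  # odd overlap v = 21: 11 columns off read 1, 10 off read 2
  r1b <- substr(tmpl, 1L, 61L)
  mb <- merge_pair(r1b, r2, tp)
  expect_identical(mb$sequence, tmpl)

  # non-overlapping spans concatenate to the sum of lengths
  r1c <- substr(tmpl, 1L, 40L)
  r2c <- epiamplicon:::revcomp(substr(tmpl, 61L, 100L))
  mc <- merge_pair(r1c, r2c, tp)
  expect_identical(nchar(mc$sequence), 80L)
  expect_identical(mc$sequence, paste0(substr(tmpl, 1, 40), substr(tmpl, 61, 100)))
})

test_that("read 2 entirely 5' of read 1 is rejected as discordant", {
  tp <- make_template(100L, 2L, seed = 52L)
  tmpl <- tp$converted_seq
  r1 <- substr(tmpl, 61L, 100L)                     # 3' chunk as read 1
  r2 <- epiamplicon:::revcomp(substr(tmpl, 1L, 40L)) # 5' chunk as read 2
  m <- merge_pair(r1, r2, tp)
  expect_identical(m$rejected, "discordant")
})

test_that("quality filter enforces 90% length then 5% gaps", {
  tp <- make_template(405L, 15L, seed = 53L)
  short <- list(sequence = strrep("A", 364L), gap_fraction = 0)
  expect_identical(quality_filter(short, tp)$reason, "short")
  ok_len <- list(sequence = strrep("A", 365L), gap_fraction = 0)
  expect_true(quality_filter(ok_len, tp)$pass)
  gappy <- list(sequence = strrep("A", 400L), gap_fraction = 0.06)
  expect_identical(quality_filter(gappy, tp)$reason, "gappy")
  both <- list(sequence = strrep("A", 100L), gap_fraction = 0.5)
  expect_identical(quality_filter(both, tp)$reason, "short")
  full <- list(sequence = tp$converted_seq, gap_fraction = 0)
  expect_true(quality_filter(full, tp)$pass)
})

test_that("zero-error full-coverage pairs all pass and merge to the molecule", {
  tp <- make_template(300L, 8L, seed = 54L)
  mix <- generate_epiallele_mixture(8L, 4L, seed = 31L)
  p <- simulate_reads(tp, mix, error_model(), 400L, read_len = 300L, seed = 15L,
                      dir = tempfile())
  fq1 <- epiamplicon:::read_fastq(p$fastq_r1)
  fq2 <- epiamplicon:::read_fastq(p$fastq_r2)
  ex <- extract_read_pairs(fq1$seqs, fq2$seqs, tp, ids = fq1$ids)
  expect_identical(unname(ex$counts["n_passed"]), 400L)
  expect_true(all(nchar(ex$merged$sequence) == 300L))
  expect_true(all(ex$merged$gap_fraction == 0))
})

test_that("the extraction tally satisfies the conservation identity", {
  tp <- make_template(250L, 6L, seed = 55L)
  mix <- generate_epiallele_mixture(6L, 4L, seed = 32L)
  em <- error_model(f_nonconv = 0.01, g_overconv = 0.01, m_subst = 0.01,
                    r_indel = 0.02, nonCpG_fail = 0.005)
  p <- simulate_reads(tp, mix, em, 150L, read_len = 160L, seed = 16L,
                      dir = tempfile())
  fq1 <- epiamplicon:::read_fastq(p$fastq_r1)
  fq2 <- epiamplicon:::read_fastq(p$fastq_r2)
  # salt in pairs that cannot match the primers
  junk <- strrep("A", 190L)
  ex <- extract_read_pairs(c(fq1$seqs, junk), c(fq2$seqs, junk), tp)
  cc <- as.list(ex$counts)
  expect_identical(cc$n_input, 151L)
  expect_identical(cc$n_extracted, cc$n_input - cc$n_primer_unmatched)
  expect_identical(cc$n_extracted,
                   cc$n_passed + cc$n_short + cc$n_gappy + cc$n_discordant)
  expect_identical(nrow(ex$merged), cc$n_extracted)
  expect_identical(as.integer(table(ex$merged$status)[c("passed")]), cc$n_passed)
})

test_that("raising the indel rate raises the gappy rejection rate", {
  tp <- make_template(250L, 6L, seed = 56L)
  mix <- generate_epiallele_mixture(6L, 3L, seed = 33L)
  gappy_at <- function(r_indel, seed) {
    em <- error_model(r_indel = r_indel)
    p <- simulate_reads(tp, mix, em, 30L, read_len = 160L, seed = seed,
                        dir = tempfile())
    fq1 <- epiamplicon:::read_fastq(p$fastq_r1)
    fq2 <- epiamplicon:::read_fastq(p$fastq_r2)
    unname(extract_read_pairs(fq1$seqs, fq2$seqs, tp)$counts["n_gappy"])
  }
  lo <- vapply(1:20, function(s) gappy_at(0.01, 100L + s), integer(1))
  hi <- vapply(1:20, function(s) gappy_at(0.10, 100L + s), integer(1))
  expect_gt(sum(hi), sum(lo))
  expect_true(mean(hi) / 30 > mean(lo) / 30)
})
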