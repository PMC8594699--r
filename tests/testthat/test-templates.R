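test_that("CpG scanning finds exactly the CG dinucleotides", {
  expect_identical(scan_cpg_sites("ACGT"), 1L)
  expect_identical(scan_cpg_sites("CGCG"), c(0L, 2L))
  expect_identical(scan_cpg_sites(""), integer(0))
  expect_identical(scan_cpg_sites("ACNGT"), integer(0))
  expect_error(scan_cpg_sites("ACGX"), "A/C/G/T/N")

  # 405-bp synthetic sequence built to contain exactly 15 CpGs, checked
  # against a brute-force dinucleotide scan
  seq <- make_seq(405L, 15L, seed = 5L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  brute <- which(chars[-length(chars)] == "C" & chars[-1L] == "G") - 1L
  expect_length(scan_cpg_sites(seq), 15L)
  expect_identical(scan_cpg_sites(seq), as.integer(brute))
})

test_that("in-silico conversion retains CpG cytosines and converts the rest", {
  expect_identical(convert_template("ACAT", integer(0)), "ATAT")
  expect_identical(convert_template("ACGT", 1L), "ACGT")
  expect_identical(convert_template("CCGG", 1L), "TCGG")
  expect_error(convert_template("AAGT", 1L), "must index 'C'")

  seq <- make_seq(300L, 8L, seed = 9L)
  conv <- convert_template(seq)
  # conversion is idempotent on its own output
  expect_identical(convert_template(conv, scan_cpg_sites(conv)), conv)
  # CpGs survive conversion
  expect_identical(scan_cpg_sites(conv), scan_cpg_sites(seq))
  # only non-CpG C positions change, and only to T
  a <- strsplit(seq, "", fixed = TRUE)[[1L]]
  b <- strsplit(conv, "", fixed = TRUE)[[1L]]
  changed <- which(a != b)
  expect_true(all(a[changed] == "C"))
  expect_true(all(b[changed] == "T"))
  expect_false(any((changed - 1L) %in% scan_cpg_sites(seq)))
})

test_that("amplicon templates validate their invariants", {
  tp <- make_template(405L, 15L, seed = 7L)
  expect_s3_class(tp, "amplicon_template")
  expect_identical(nchar(tp$genomic_seq), tp$length_bp)
  expect_identical(nchar(tp$converted_seq), tp$length_bp)
  g <- strsplit(tp$genomic_seq, "", fixed = TRUE)[[1L]]
  expect_true(all(g[tp$cpg_positions + 1L] == "C"))
  expect_true(all(g[tp$cpg_positions + 2L] == "G"))
  expect_true(all(diff(tp$cpg_positions) > 0L))
  expect_false((tp$length_bp - 1L) %in% tp$cpg_positions)

  expect_error(amplicon_template("x", "ACGNT", strrep("A", 33), strrep("A", 33)),
               "no N")
  expect_error(amplicon_template("x", "ACGTACGT", strrep("A", 29), strrep("A", 33)),
               "primer_fwd")
  expect_error(
    amplicon_template("x", make_seq(100L, 2L, 1L), strrep("A", 33),
                      strrep("A", 33), cpg_positions = c(5L, 6L)),
    "cpg_positions")
})

test_that("panel round-trips through FASTA + TOML config", {
  panel <- make_panel(seed = 33L)
  fa <- tempfile(fileext = ".fasta")
  cfg <- tempfile(fileext = ".toml")
  write_panel(panel, fa, cfg)
  back <- load_panel(fa, cfg)
  expect_identical(names(back), names(panel))
  for (nm in names(panel)) {
    expect_identical(unclass(back[[nm]]), unclass(panel[[nm]]))
  }
  # panel geometry mirrors the three-amplicon design: 10/10/15 CpGs
  expect_identical(vapply(back, function(t) length(t$cpg_positions), integer(1)),
                   c(dynA = 10L, pkcB = 10L, nadC = 15L))
  expect_identical(vapply(back, `[[`, integer(1), "length_bp"),
                   c(dynA = 551L, pkcB = 401L, nadC = 405L))
})

test_that("panel config errors name the offending field", {
  panel <- make_panel(seed = 34L)
  fa <- tempfile(fileext = ".fasta")
  cfg <- tempfile(fileext = ".toml")
  write_panel(panel, fa, cfg)

  # config omitting cpg_positions derives them from the sequence
  lines <- readLines(cfg)
  writeLines(grep("cpg_positions", lines, value = TRUE, invert = TRUE), cfg)
  back <- load_panel(fa, cfg)
  expect_identical(back$nadC$cpg_positions, panel$nadC$cpg_positions)

  # record missing from FASTA
  writeLines(sub('name = "dynA"', 'name = "ghost"', lines), cfg)
  expect_error(load_panel(fa, cfg), "ghost")

  # short primer
  writeLines(sub('primer_fwd = "([A-Z]{4})[A-Z]*"', 'primer_fwd = "\\1"', lines),
             cfg)
  expect_error(load_panel(fa, cfg), "primer")

  # invalid CpG coordinate
  writeLines(sub("cpg_positions = \\[[0-9]+", "cpg_positions = [2", lines), cfg)
  expect_error(load_panel(fa, cfg), "cpg_positions")
})
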