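test_that("with a zero-error channel the estimate is the empirical distribution", {
  tab <- tabulate_patterns(c(rep("101", 6L), rep("010", 3L), "111"))
  fit <- fit_pattern_mixture(tab, error_model(), support_cut = 0)
  expect_equal(fit$freqs[c("101", "010", "111")],
               c("101" = 0.6, "010" = 0.3, "111" = 0.1), tolerance = 1e-12)
  expect_identical(length(fit$eliminated), 0L)

  single <- fit_pattern_mixture(tabulate_patterns(rep("1100", 5L)), error_model())
  expect_identical(unname(single$freqs), 1)
  expect_identical(names(single$freqs), "1100")
})

test_that("two dominant patterns are recovered and spurious ones eliminated", {
  mix <- epiallele_mixture(c("0110", "1001"), c(0.7, 0.3))
  em <- error_model(f_nonconv = 0.01, g_overconv = 0.01, m_subst = 0.003)
  pats <- simulate_observed_patterns(mix, em, 10000L, seed = 81L)
  tab <- tabulate_patterns(pats)
  expect_gt(length(tab$counts), 2L)  # error channel creates spurious patterns
  fit <- fit_pattern_mixture(tab, em)
  expect_identical(sort(names(fit$freqs)), c("0110", "1001"))
  expect_lt(abs(fit$freqs[["0110"]] - 0.7), 0.02)
  expect_lt(abs(fit$freqs[["1001"]] - 0.3), 0.02)
})

test_that("the EM log-likelihood never decreases", {
  set.seed(91L)
  for (case in 1:5) {
    tab <- random_pattern_counts(n_cpgs = 6L, k = 4L, n = 2000L, seed = 200L + case)
    em <- error_model(f_nonconv = 0.02, g_overconv = 0.01, m_subst = 0.005)
    fit <- fit_pattern_mixture(tab, em, support_cut = 0)
    expect_true(all(diff(fit$ll_trace) >= -1e-9))
    expect_true(fit$converged)
  }
})

test_that("EM frequencies match the brute-force likelihood optimizer", {
  set.seed(92L)
  for (case in 1:6) {
    n_cpgs <- sample(3:4, 1L)
    k <- sample(3:6, 1L)
    mix <- generate_epiallele_mixture(n_cpgs, k, concentration = 1.5,
                                      seed = 300L + case)
    em <- error_model(f_nonconv = 0.03, g_overconv = 0.02, m_subst = 0.01)
    pats <- simulate_observed_patterns(mix, em, 800L, seed = 400L + case)
    tab <- tabulate_patterns(pats)
    if (length(tab$counts) > 6L) {
      keep <- names(tab$counts)[1:6]
      tab <- tabulate_patterns(rep(keep, times = tab$counts[keep]))
    }
    fit <- fit_pattern_mixture(tab, em, support_cut = 0, lrt_cut = 0)
    want <- oracle_fit_freqs(tab$counts, em)
    expect_lt(max(abs(fit$freqs[names(want)] - want)), 1e-4)
  }
})

test_that("raising the support cut never enlarges the support", {
  tab <- random_pattern_counts(n_cpgs = 8L, k = 6L, n = 5000L, seed = 95L)
  em <- error_model(f_nonconv = 0.02, g_overconv = 0.02, m_subst = 0.01)
  sizes <- vapply(c(0, 1e-4, 1e-3, 1e-2, 5e-2),
                  function(cut) length(fit_pattern_mixture(tab, em,
                                                           support_cut = cut)$freqs),
                  integer(1))
  expect_true(all(diff(sizes) <= 0L))
})

test_that("reporting cutoffs retain patterns without renormalizing", {
  freqs <- c(A = 0.60, B = 0.35, C = 0.04, D = 0.01)
  at5 <- apply_cutoff(freqs, 0.05)
  expect_identical(at5$patterns, c("A", "B"))
  expect_identical(unname(at5$retained), c(0.60, 0.35))
  expect_equal(at5$retained_mass, 0.95)

  expect_identical(apply_cutoff(freqs, 0)$patterns, names(freqs))

  # 5% support is nested within 1% support
  tab <- random_pattern_counts(n_cpgs = 10L, k = 8L, n = 4000L, seed = 96L)
  fit <- fit_pattern_mixture(tab, error_model(), support_cut = 0)
  expect_true(all(apply_cutoff(fit, 0.05)$patterns %in%
                    apply_cutoff(fit, 0.01)$patterns))
})

test_that("fit methods expose frequencies, likelihood and predictions", {
  tab <- random_pattern_counts(n_cpgs = 5L, k = 3L, n = 1000L, seed = 97L)
  em <- error_model(f_nonconv = 0.01, g_overconv = 0.01, m_subst = 0.005)
  fit <- fit_pattern_mixture(tab, em)
  expect_identical(coef(fit), fit$freqs)
  expect_s3_class(logLik(fit), "logLik")
  pr <- predict(fit)
  expect_true(all(pr > 0) && sum(pr) <= 1 + 1e-9)
  sim <- simulate(fit, nsim = 2L, seed = 5L)
  expect_length(sim, 2L)
  expect_identical(sum(sim[[1L]]), fit$n_reads)
  expect_error(fit_pattern_mixture(tabulate_patterns(character(0)), em), "empty")
  expect_error(fit_pattern_mixture(tab, error_model(f_nonconv = 0.6)), "below 0.5")
})
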