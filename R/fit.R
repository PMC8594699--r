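# Maximum-likelihood estimation of the true methylation-pattern distribution
# from observed pattern counts, under an explicit conversion/sequencing error
# model, with elimination of spurious (error-generated) patterns.

# Per-site flip probabilities of the observation channel.
flip_probs <- function(error_model) {
  f <- error_model$f_nonconv
  g <- error_model$g_overconv
  m <- error_model$m_subst
  c(p01 = f * (1 - m) + (1 - f) * m,   # true 0 observed as 1
    p10 = g * (1 - m) + (1 - g) * m)   # true 1 observed as 0
}

# log P(observed pattern o | true pattern t) for all pairs; rows = observed,
# cols = candidate true patterns. Zero flip probabilities are handled exactly
# (-Inf off the diagonal of agreement).
emission_loglik <- function(O, Tm, p01, p10) {
  n01 <- O %*% t(1 - Tm)       # sites observed 1, true 0
  n00 <- (1 - O) %*% t(1 - Tm)
  n10 <- (1 - O) %*% t(Tm)     # sites observed 0, true 1
  n11 <- O %*% t(Tm)
  term <- function(n, p) {
    if (p == 0) ifelse(n > 0, -Inf, 0) else n * log(p)
  }
  term(n01, p01) + term(n00, 1 - p01) + term(n10, p10) + term(n11, 1 - p10)
}

log_sum_exp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# One EM run over a fixed candidate support. Returns frequencies, the
# log-likelihood trace, and convergence information.
em_run <- function(counts_obs, logE, pi0, tol, max_iter) {
  n <- sum(counts_obs)
  pi <- pi0
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lp <- sweep(logE, 2L, ifelse(pi > 0, log(pi), -Inf), `+`)
    lse <- log_sum_exp_rows(lp)
    ll <- sum(counts_obs * lse)
    if (length(ll_trace) && ll < ll_old - 1e-9) {
      stop("internal error: EM log-likelihood decreased")
    }
    ll_trace <- c(ll_trace, ll)
    if (!is.finite(ll) && length(ll_trace) > 1L) break  # support cannot emit data
    R <- exp(lp - lse)
    R[!is.finite(lse), ] <- 0
    pi <- as.numeric(crossprod(R, counts_obs)) / n
    if (is.finite(ll) && is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(pi = pi, ll_trace = ll_trace, converged = converged, n_iter = length(ll_trace))
}

#' Estimate the true pattern distribution from observed counts
#'
#' Fits a multinomial mixture to an observed pattern count table: each
#' candidate true pattern t emits observed patterns through an independent
#' per-site error channel with P(observe 1 | true 0) =
#' \code{f_nonconv (1 - m_subst) + (1 - f_nonconv) m_subst} and
#' P(observe 0 | true 1) = \code{g_overconv (1 - m_subst) + (1 - g_overconv)
#' m_subst}. The candidate support is the set of observed patterns; mixture
#' frequencies are obtained by EM (initialized at the empirical frequencies,
#' tolerance on the log-likelihood increment, iteration cap).
#'
#' Spurious, error-generated patterns are then eliminated in two stages.
#' First, patterns whose estimated frequency falls below \code{support_cut}
#' are removed, the remainder renormalized and the EM re-run, iterating to a
#' fixed point. Second, each surviving pattern is screened by a likelihood
#' ratio: the model is refit without it, and the pattern is removed when twice
#' the log-likelihood drop stays below \code{lrt_cut}; the least significant
#' pattern is removed first and the screen repeated. At ultra-deep read counts
#' the count threshold alone is insufficient, because chance excursions in the
#' tally of an error neighbour of a dominant pattern push its maximum-
#' likelihood frequency past any small fixed cut; the ratio screen asks
#' instead whether the pattern explains anything the error channel cannot.
#'
#' With all error rates zero the channel is the identity, every observed
#' pattern is its own only explanation, and the estimate equals the empirical
#' frequencies with nothing eliminated.
#'
#' @param counts A \code{\link{tabulate_patterns}} table (or a named integer
#'   vector of observed pattern counts).
#' @param error_model An \code{\link{error_model}}; rates must be below 0.5.
#' @param support_cut Elimination threshold on estimated frequencies; default
#'   \code{10 / n_reads}.
#' @param lrt_cut Chi-square threshold of the likelihood-ratio screen;
#'   default \code{qchisq(1 - 0.01 / K, df = 1)} with K the number of observed
#'   patterns (a familywise 1\% screen). Set to 0 to disable.
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum EM iterations per run (default 10000).
#' @return An object of class \code{pattern_fit} with fields \code{freqs}
#'   (named, descending), \code{eliminated}, \code{counts}, \code{error_model},
#'   \code{n_reads}, \code{support_cut}, \code{logLik}, \code{ll_trace},
#'   \code{n_iter}, \code{converged}, \code{amplicon}, \code{sample}.
#' @seealso \code{\link{apply_cutoff}}, \code{\link{per_cpg_levels}}
#' @export
fit_pattern_mixture <- function(counts, error_model = error_model(),
                                support_cut = NULL, lrt_cut = NULL,
                                tol = 1e-8, max_iter = 10000L) {
  if (inherits(counts, "pattern_counts")) {
    amplicon <- counts$amplicon
    sample <- counts$sample
    cnt <- counts$counts
  } else {
    amplicon <- sample <- NA_character_
    cnt <- counts
  }
  if (!length(cnt) || sum(cnt) == 0) stop("empty pattern count table")
  stopifnot(inherits(error_model, "error_model"))
  fp <- flip_probs(error_model)
  if (any(fp >= 0.5)) stop("error rates must give flip probabilities below 0.5")
  n_reads <- sum(cnt)
  if (is.null(support_cut)) support_cut <- 10 / n_reads
  if (is.null(lrt_cut)) lrt_cut <- stats::qchisq(1 - 0.01 / length(cnt), df = 1)

  obs <- names(cnt)
  O <- pattern_matrix(obs)
  support <- obs
  pi <- as.numeric(cnt) / n_reads
  eliminated <- character(0)
  fit <- NULL
  refit <- function(sup, pi0) {
    logE <- emission_loglik(O, pattern_matrix(sup), fp["p01"], fp["p10"])
    em_run(as.numeric(cnt), logE, pi0, tol, max_iter)
  }
  # stage 1: frequency threshold, iterated to a fixed point
  repeat {
    fit <- refit(support, pi)
    drop <- fit$pi < support_cut
    if (!any(drop) || all(drop)) break
    eliminated <- c(eliminated, support[drop])
    support <- support[!drop]
    pi <- fit$pi[!drop] / sum(fit$pi[!drop])
  }
  # stage 2: likelihood-ratio screen, least significant pattern first
  if (lrt_cut > 0 && length(support) > 1L) {
    repeat {
      ll_full <- fit$ll_trace[fit$n_iter]
      stat <- numeric(length(support))
      for (k in seq_along(support)) {
        sub <- support[-k]
        logE_sub <- emission_loglik(O, pattern_matrix(sub), fp["p01"], fp["p10"])
        if (any(cnt > 0 & !is.finite(apply(logE_sub, 1L, max)))) {
          stat[k] <- Inf  # remaining support cannot emit an observed pattern
          next
        }
        pi0 <- fit$pi[-k]
        pi0 <- if (sum(pi0) > 0) pi0 / sum(pi0) else rep(1 / length(sub), length(sub))
        f2 <- em_run(as.numeric(cnt), logE_sub, pi0, tol, max_iter)
        stat[k] <- 2 * (ll_full - f2$ll_trace[f2$n_iter])
      }
      worst <- which.min(stat)
      if (stat[worst] >= lrt_cut || length(support) <= 1L) break
      eliminated <- c(eliminated, support[worst])
      support <- support[-worst]
      pi <- fit$pi[-worst]
      pi <- if (sum(pi) > 0) pi / sum(pi) else rep(1 / length(support), length(support))
      fit <- refit(support, pi)
      if (length(support) == 1L) break
    }
  }
  freqs <- fit$pi / sum(fit$pi)
  names(freqs) <- support
  ord <- order(-freqs, names(freqs))
  freqs <- freqs[ord]
  structure(list(freqs = freqs, eliminated = sort(eliminated), counts = cnt,
                 error_model = error_model, n_reads = n_reads,
                 support_cut = support_cut, lrt_cut = lrt_cut,
                 logLik = fit$ll_trace[fit$n_iter],
                 ll_trace = fit$ll_trace, n_iter = fit$n_iter,
                 converged = fit$converged, amplicon = amplicon, sample = sample),
            class = "pattern_fit")
}

#' @export
print.pattern_fit <- function(x, n = 10L, ...) {
  cat("Estimated methylation pattern distribution")
  if (!is.na(x$amplicon)) cat(" (amplicon '", x$amplicon, "', sample '",
                              x$sample, "')", sep = "")
  cat("\n  ", length(x$freqs), " retained patterns from ", length(x$counts),
      " observed (", length(x$eliminated), " eliminated as spurious), n = ",
      x$n_reads, " reads\n", sep = "")
  show <- head(x$freqs, n)
  print(data.frame(pattern = names(show), frequency = signif(unname(show), 4)))
  if (length(x$freqs) > n) cat("... and", length(x$freqs) - n, "more\n")
  invisible(x)
}

#' @export
summary.pattern_fit <- function(object, ...) {
  lv <- per_cpg_levels(object)
  cat("Pattern mixture fit: ", length(object$freqs), " patterns, n = ",
      object$n_reads, " reads, logLik = ", format(object$logLik), ", ",
      object$n_iter, " EM iterations (",
      if (object$converged) "converged" else "not converged", ")\n", sep = "")
  cat("Support cut: ", signif(object$support_cut, 3), "; eliminated ",
      length(object$eliminated), " spurious patterns\n", sep = "")
  cat("Per-CpG combined levels:\n")
  print(round(lv, 4))
  cat("Overall methylation level:", round(mean(lv), 4), "\n")
  invisible(object)
}

#' @export
coef.pattern_fit <- function(object, ...) object$freqs

#' @export
logLik.pattern_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$freqs) - 1L, class = "logLik")
}

#' @export
per_cpg_levels.pattern_fit <- function(x, ...) per_cpg_levels.default(x$freqs)

#' Expected observed-pattern probabilities under a fit
#'
#' Pushes the estimated true-pattern frequencies through the error channel,
#' giving the probability of each observed pattern under the fitted model.
#'
#' @param object A \code{pattern_fit}.
#' @param patterns Observed patterns to evaluate (defaults to the observed
#'   support of the fit).
#' @param ... Unused.
#' @return Named numeric vector of probabilities.
#' @export
predict.pattern_fit <- function(object, patterns = names(object$counts), ...) {
  fp <- flip_probs(object$error_model)
  logE <- emission_loglik(pattern_matrix(patterns), pattern_matrix(names(object$freqs)),
                          fp["p01"], fp["p10"])
  pr <- as.numeric(exp(logE) %*% object$freqs)
  names(pr) <- patterns
  pr
}

#' Simulate observed pattern counts from a fit
#'
#' Parametric resampling: molecules are drawn from the fitted true-pattern
#' distribution and passed through the fitted error channel.
#'
#' @param object A \code{pattern_fit}.
#' @param nsim Number of replicate tables.
#' @param seed Integer seed.
#' @param n_reads Reads per replicate (defaults to the fit's).
#' @param ... Unused.
#' @return List of named count vectors.
#' @export
simulate.pattern_fit <- function(object, nsim = 1L, seed = 1L,
                                 n_reads = object$n_reads, ...) {
  mix <- epiallele_mixture(names(object$freqs), unname(object$freqs))
  lapply(seq_len(nsim), function(i) {
    pats <- simulate_observed_patterns(mix, object$error_model, n_reads,
                                       seed = seed + i - 1L)
    tabulate_patterns(pats)$counts
  })
}

#' Apply a reporting frequency cutoff to a fitted distribution
#'
#' Retains the patterns whose estimated frequency is at least \code{cutoff},
#' keeping their original (non-renormalized) frequencies, as used for the 1\%
#' and 5\% minimum-frequency reporting levels.
#'
#' @param fit A \code{pattern_fit} (or named numeric frequency vector).
#' @param cutoff Fraction in \code{[0, 1]}.
#' @return List with \code{retained} (named frequencies), \code{patterns}
#'   (character), \code{retained_mass}, and \code{cutoff}.
#' @export
apply_cutoff <- function(fit, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  freqs <- if (inherits(fit, "pattern_fit")) fit$freqs else fit
  keep <- freqs >= cutoff
  list(retained = freqs[keep], patterns = names(freqs)[keep],
       retained_mass = sum(freqs[keep]), cutoff = cutoff)
}

#' Write / read an estimated pattern distribution
#'
#' TSV with columns amplicon, sample, pattern, est_frequency, observed_count.
#'
#' @param fit A \code{pattern_fit}.
#' @param path Output path.
#' @return \code{path}, invisibly (writer); a data.frame (reader).
#' @export
write_distribution <- function(fit, path) {
  df <- data.frame(amplicon = fit$amplicon, sample = fit$sample,
                   pattern = names(fit$freqs), est_frequency = unname(fit$freqs),
                   observed_count = as.integer(fit$counts[names(fit$freqs)]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  read.delim(path, colClasses = c(pattern = "character"))
}
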