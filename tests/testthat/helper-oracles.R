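# Independent oracles used by the tests.  Each re-derives the quantity it
# checks by a different route from the implementation under test.

# Brute-force dynamic-programming alignment oracle: plain R, three explicit
# state matrices, same scoring contract as the package aligner (bisulfite
# match, affine gap of length k costs open + k*ext, free end gaps on the read
# row, diagonal > up > left tie-break, rightmost best end column).
oracle_align <- function(read, tmpl, match = 2L, mismatch = -3L,
                         gap_open = 5L, gap_ext = 2L) {
  r <- strsplit(read, "", fixed = TRUE)[[1L]]
  t <- strsplit(tmpl, "", fixed = TRUE)[[1L]]
  n <- length(r); m <- length(t)
  NEG <- -1e9
  M <- IY <- IX <- matrix(NEG, n + 1L, m + 1L)
  tbM <- tbY <- tbX <- matrix(0L, n + 1L, m + 1L)
  M[1L, ] <- 0
  for (i in seq_len(n)) {
    IY[i + 1L, 1L] <- -(gap_open + i * gap_ext)
    tbY[i + 1L, 1L] <- if (i == 1L) 1L else 2L  # column-0 gap run ends at (0,0)
  }
  score_of <- function(a, b) if (a == b || (a == "T" && b == "C")) match else mismatch
  argmax3 <- function(v) which.max(v)  # ties -> lowest index = preference order
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      sc <- score_of(r[i - 1L], t[j - 1L])
      cand <- c(M[i - 1L, j - 1L], IY[i - 1L, j - 1L], IX[i - 1L, j - 1L])
      k <- argmax3(cand); M[i, j] <- cand[k] + sc; tbM[i, j] <- k
      cand <- c(M[i - 1L, j] - gap_open - gap_ext,
                IY[i - 1L, j] - gap_ext,
                IX[i - 1L, j] - gap_open - gap_ext)
      k <- argmax3(cand); IY[i, j] <- cand[k]; tbY[i, j] <- k
      cand <- c(M[i, j - 1L] - gap_open - gap_ext,
                IY[i, j - 1L] - gap_open - gap_ext,
                IX[i, j - 1L] - gap_ext)
      k <- argmax3(cand); IX[i, j] <- cand[k]; tbX[i, j] <- k
    }
  }
  best <- NEG; bj <- 1L; bst <- 1L
  for (j in seq_len(m + 1L)) {
    cand <- c(M[n + 1L, j], IY[n + 1L, j], IX[n + 1L, j])
    k <- argmax3(cand)
    if (cand[k] >= best) { best <- cand[k]; bj <- j; bst <- k }
  }
  i <- n + 1L; j <- bj; st <- bst
  ra <- ta <- character(0)
  while (i > 1L) {
    if (st == 1L) {
      ra <- c(r[i - 1L], ra); ta <- c(t[j - 1L], ta)
      st <- tbM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (st == 2L) {
      ra <- c(r[i - 1L], ra); ta <- c("-", ta)
      st <- tbY[i, j]; i <- i - 1L
    } else {
      ra <- c("-", ra); ta <- c(t[j - 1L], ta)
      st <- tbX[i, j]; j <- j - 1L
    }
  }
  list(read_aln = paste(ra, collapse = ""), template_aln = paste(ta, collapse = ""),
       score = best, start = j - 1L, end = bj - 1L)
}

# Brute-force constrained-likelihood oracle for the mixture estimator:
# maximizes the same multinomial likelihood over the simplex by multi-start
# quasi-Newton optimization of softmax-parameterized frequencies.  The
# log-likelihood is concave in the frequencies, so local optima are global.
oracle_fit_freqs <- function(counts, error_model) {
  obs <- names(counts)
  n_o <- as.numeric(counts)
  fp <- epiamplicon:::flip_probs(error_model)
  E <- exp(epiamplicon:::emission_loglik(epiamplicon:::pattern_matrix(obs),
                                         epiamplicon:::pattern_matrix(obs),
                                         fp["p01"], fp["p10"]))
  nll <- function(theta) {
    pi <- exp(theta - max(theta)); pi <- pi / sum(pi)
    -sum(n_o * log(pmax(E %*% pi, 1e-300)))
  }
  starts <- list(log(pmax(n_o / sum(n_o), 1e-6)))
  set.seed(42L)
  for (s in 1:4) starts[[s + 1L]] <- rnorm(length(obs))
  best <- NULL
  for (th0 in starts) {
    o <- optim(th0, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  pi <- exp(best$par - max(best$par)); pi <- pi / sum(pi)
  names(pi) <- obs
  pi
}

# Exhaustive membership-vector enumeration for exclusive Venn regions.
oracle_venn <- function(sets) {
  pats <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  out <- integer(0)
  for (size in seq_len(k)) {
    for (comb in utils::combn(seq_len(k), size, simplify = FALSE)) {
      cnt <- 0L
      for (p in pats) {
        inside <- vapply(seq_len(k), function(i) p %in% sets[[i]], logical(1))
        if (all(inside[comb]) && !any(inside[-comb])) cnt <- cnt + 1L
      }
      out[paste(names(sets)[comb], collapse = "&")] <- cnt
    }
  }
  out
}
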