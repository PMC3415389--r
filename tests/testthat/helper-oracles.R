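# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: tail probabilities are summed from
# binomial-coefficient terms, scans are per-position loops.

# P(X >= k) for hypergeometric: K marked among N, n drawn.
hyper_tail_oracle <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  total <- choose(N, n)
  sum(vapply(k:hi, function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1L))) / total
}

# P(X >= k) for Binomial(n, p).
binom_tail_oracle <- function(k, n, p) {
  if (k > n) return(0)
  sum(vapply(k:n, function(x)
    choose(n, x) * p^x * (1 - p)^(n - x), numeric(1L)))
}

# P(X >= k) for Poisson(lambda): the upper tail is summed directly so tiny
# tails are not lost to cancellation.
pois_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  x <- k:(k + 400)
  sum(exp(-lambda + x * log(lambda) - lgamma(x + 1)))
}

base_rc <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
rc_oracle <- function(s) {
  paste(rev(base_rc[strsplit(s, "")[[1L]]]), collapse = "")
}

# Per-position PWM rescoring, both strands, no shortcuts.
naive_scan_oracle <- function(pwm, sequence) {
  chars <- strsplit(sequence, "")[[1L]]
  w <- pwm$width
  score_at <- function(mat, p) {
    s <- 0
    for (j in seq_len(w)) {
      b <- chars[p + j - 1L]
      if (b %in% c("A", "C", "G", "T")) s <- s + mat[b, j]
    }
    s
  }
  rmat <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(w)), drop = FALSE]
  rownames(rmat) <- c("A", "C", "G", "T")
  out <- NULL
  for (p in seq_len(length(chars) - w + 1L)) {
    for (str in c("+", "-")) {
      sc <- score_at(if (str == "+") pwm$mat else rmat, p)
      if (sc >= pwm$threshold)
        out <- rbind(out, data.frame(pos = p - 1L, strand = str, score = sc))
    }
  }
  out
}

# Naive multi-pattern accumulation of prior counts: per member k-mer, per
# position substring comparison on both strands.
naive_prior_oracle <- function(members, region_seq) {
  M <- nchar(region_seq)
  C <- integer(M)
  for (i in seq_len(nrow(members))) {
    km <- members$kmer[i]
    k <- nchar(km)
    off <- as.integer(round(members$offset[i]))
    rc <- rc_oracle(km)
    starts <- seq_len(M - k + 1L)
    subs <- substring(region_seq, starts, starts + k - 1L)
    for (s in starts[subs == km]) {
      b <- (s - 1L) + off
      if (b >= 0L && b < M) C[b + 1L] <- C[b + 1L] + members$pos_hits[i]
    }
    if (km != rc) for (s in starts[subs == rc]) {
      b <- (s - 1L) + (k - 1L) - off
      if (b >= 0L && b < M) C[b + 1L] <- C[b + 1L] + members$pos_hits[i]
    }
  }
  C
}

# Hand-built region (bypasses segmentation) for direct em_fit tests.
manual_region <- function(pos5, strand, start, end, chrom = "chr1") {
  list(chrom = chrom, start = as.integer(start), end = as.integer(end),
       reads = data.table::data.table(chrom = chrom,
                                      pos5 = as.integer(pos5),
                                      strand = strand))
}

random_seqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), "")
}

# gem_pwm straight from a probability matrix against a uniform background.
pwm_from_prob <- function(prob, background = rep(0.25, 4L)) {
  chipem:::new_gem_pwm(log2(prob / background), prob, background)
}

# Best mean per-column Pearson correlation between a discovered PWM and a
# truth probability matrix, over both orientations and all overlapping
# alignments of at least 5 columns.
pwm_truth_cor <- function(pwm, truth) {
  best <- -1
  for (m in list(pwm$prob,
                 pwm$prob[4:1, rev(seq_len(ncol(pwm$prob))), drop = FALSE])) {
    w1 <- ncol(m); w2 <- ncol(truth)
    for (sh in -(w1 - 5):(w2 - 5)) {
      j1 <- max(1L, 1L - sh); j2 <- min(w1, w2 - sh)
      if (j2 - j1 + 1L < 5L) next
      cc <- mean(vapply(j1:j2, function(j)
        stats::cor(m[, j], truth[, j + sh]), numeric(1)))
      if (!is.na(cc)) best <- max(best, cc)
    }
  }
  best
}

# TRUE when the discovered consensus (either orientation) shares a
# contiguous >= min_len substring with the planted consensus.
consensus_matches <- function(cons, truth_cons, min_len = 6L) {
  for (c2 in c(cons, rc_oracle(cons))) {
    n <- nchar(truth_cons)
    for (s in seq_len(n - min_len + 1L))
      if (grepl(substr(truth_cons, s, s + min_len - 1L), c2, fixed = TRUE))
        return(TRUE)
  }
  FALSE
}
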