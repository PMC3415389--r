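## Phases 2-3 and 6: k-mer enrichment, equivalence-class clustering,
## weighted PWM construction and trimming, secondary motif search.

# byte lookup: A,C,G,T -> 1..4; everything else (incl. N) -> 5
.code_lut <- local({
  lut <- rep(5L, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("a")] <- 1L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("g")] <- 3L; lut[utf8ToInt("t")] <- 4L
  lut
})

codes_of <- function(seq) .code_lut[as.integer(charToRaw(seq))]

#' Reverse complement of character sequences
#' @param x Character vector over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonical form under reverse complement: lexicographically smaller of the
# k-mer and its reverse complement.
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

kmer_hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vapply(strsplit(b, "", fixed = TRUE), function(vb) sum(va != vb),
         integer(1L))
}

# Zero-order base model (A,C,G,T frequencies) from a sequence set,
# both strands so the background is strand-symmetric.
base_background <- function(seqs) {
  codes <- unlist(lapply(seqs, codes_of), use.names = FALSE)
  cnt <- tabulate(codes[codes <= 4L], nbins = 4L)
  cnt <- cnt + rev(cnt)  # add reverse complement
  if (sum(cnt) == 0L) return(rep(0.25, 4L))
  cnt / sum(cnt)
}

#' Extract positive and negative sequence sets around events
#'
#' Positive sequences are \code{2*flank + 1} bp windows (61 bp by default)
#' centered on the event positions; negatives are same-width windows
#' centered 300 bp up- and downstream of each event, dropped when they
#' overlap any positive window or run off the contig. Events without full
#' clearance for their positive window are skipped with a message.
#'
#' @param events Event table (\code{chrom}, \code{pos}, optionally
#'   \code{strength}).
#' @param genome A \code{DNAStringSet}.
#' @param flank Half-width of the windows (bp).
#' @param neg_offset Distance from event to negative window centers (bp).
#' @return List with \code{pos} (data.table \code{seq}, \code{chrom},
#'   \code{start}, \code{event_pos}, \code{strength}, \code{center} =
#'   1-based index of the event base in \code{seq}), \code{neg}
#'   (data.table \code{seq}, \code{chrom}, \code{start}) and \code{flank}.
#' @export
extract_sets <- function(events, genome, flank = 30L, neg_offset = 300L) {
  lens <- genome_lengths(genome)
  width <- 2L * flank + 1L
  events <- data.table::as.data.table(events)
  if (!"strength" %in% names(events)) events$strength <- 1
  ok <- events$pos - flank >= 0 &
    events$pos + flank < lens[events$chrom] &
    events$chrom %in% names(lens)
  if (any(!ok))
    message("extract_sets: skipped ", sum(!ok),
            " event(s) too close to a contig edge")
  events <- events[ok, ]
  # one character conversion per chromosome, then plain substring windows
  chrom_str <- lapply(stats::setNames(nm = unique(events$chrom)), function(ch)
    toupper(as.character(genome[[ch]])))
  win <- function(ch, start)
    substr(chrom_str[[ch]], start + 1L, start + width)
  pos <- data.table::data.table(
    seq = mapply(win, events$chrom, events$pos - flank, USE.NAMES = FALSE),
    chrom = events$chrom, start = events$pos - flank,
    event_pos = events$pos, strength = events$strength,
    center = flank + 1L)
  # candidate negatives at +/- neg_offset from each event
  cand <- data.table::data.table(
    chrom = rep(events$chrom, 2L),
    start = c(events$pos - neg_offset - flank, events$pos + neg_offset - flank))
  cand <- cand[cand$start >= 0 & cand$start + width <= lens[cand$chrom], ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- pos[pos$chrom == cand$chrom[i], ]
    if (any(cand$start[i] < p$start + width & p$start < cand$start[i] + width))
      keep[i] <- FALSE
  }
  cand <- cand[keep, ]
  neg <- data.table::data.table(
    seq = mapply(win, cand$chrom, cand$start, USE.NAMES = FALSE),
    chrom = cand$chrom, start = cand$start)
  if (nrow(neg) == 0L) neg$seq <- character(0)
  list(pos = pos, neg = neg, flank = flank)
}

# All valid (N-free) k-mer occurrences in a set of sequences:
# data.table(seq_id, s (0-based start), canon, fwd (canonical appears in
# forward orientation)). Palindromes are marked forward.
kmer_occurrences <- function(seqs, k) {
  occ <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    valid <- !grepl("[^ACGT]", km)
    if (!any(valid)) return(NULL)
    data.table::data.table(seq_id = i, s = starts[valid] - 1L,
                           kmer = km[valid])
  })
  occ <- data.table::rbindlist(occ)
  if (nrow(occ) == 0L) {
    occ$canon <- character(0); occ$fwd <- logical(0)
    return(occ)
  }
  u <- unique(occ$kmer)
  canon_u <- canonical_kmer(u)
  idx <- match(occ$kmer, u)
  occ$canon <- canon_u[idx]
  occ$fwd <- occ$kmer == occ$canon
  occ
}

#' Find k-mers enriched in positive over negative sequences
#'
#' A k-mer and its reverse complement are treated as the same sequence
#' (canonical form). Hit counting is per-sequence presence, not occurrence
#' count. Enrichment is the hypergeometric upper-tail p-value of the
#' positive hit count given the combined hits, and the fold ratio of hit
#' frequencies (negative hits floored at 1 for the ratio). A k-mer is
#' returned when \code{p < p_cut} and \code{fold >= fold_min}. Each
#' returned k-mer carries its expected signed offset from the binding
#' event, averaged over its occurrences in the positive set (an occurrence
#' at 0-based start \code{s} in canonical-forward orientation implies the
#' event at \code{s + offset}).
#'
#' @param pos,neg Character vectors of positive / negative sequences.
#' @param k k-mer length (5 to 13 in the standard pipeline).
#' @param p_cut Hypergeometric p-value gate (default 0.001).
#' @param fold_min Minimum fold enrichment (default 3).
#' @param center 1-based index of the event base in positive sequences;
#'   defaults to the middle base.
#' @return data.table(\code{kmer}, \code{k}, \code{pos_hits},
#'   \code{neg_hits}, \code{p_hyper}, \code{fold}, \code{offset}), ordered
#'   by ascending p, descending fold, then lexicographically.
#' @export
find_enriched_kmers <- function(pos, neg, k, p_cut = 1e-3, fold_min = 3,
                                center = NULL) {
  if (k > min(nchar(c(pos, neg))))
    stop("k = ", k, " exceeds the shortest sequence length")
  if (is.null(center)) center <- (min(nchar(pos)) + 1L) %/% 2L
  np <- length(pos); nn <- length(neg)
  po <- kmer_occurrences(pos, k)
  no <- kmer_occurrences(neg, k)
  if (nrow(po) == 0L) return(empty_kmer_table())
  # signed event offset, canonical-forward frame; one occurrence per
  # sequence (the one nearest the event) represents that sequence
  po$d <- ifelse(po$fwd, (center - 1L) - po$s, po$s + k - 1L - (center - 1L))
  po$dctr <- abs(po$s + (k - 1L) / 2 - (center - 1L))
  data.table::setorderv(po, c("canon", "seq_id", "dctr", "s"))
  rep1 <- po[!duplicated(po[, c("canon", "seq_id")]), ]
  ph <- rep1[, list(pos_hits = .N, offset = mean(d)), by = "canon"]
  nh <- if (nrow(no) > 0L) {
    no[, list(neg_hits = length(unique(seq_id))), by = "canon"]
  } else data.table::data.table(canon = character(), neg_hits = integer())
  tab <- merge(ph, nh, by = "canon", all.x = TRUE)
  tab$neg_hits[is.na(tab$neg_hits)] <- 0L
  K <- tab$pos_hits + tab$neg_hits
  tab$p_hyper <- stats::phyper(tab$pos_hits - 1L, K, np + nn - K, np,
                               lower.tail = FALSE)
  tab$fold <- (tab$pos_hits / np) / (pmax(tab$neg_hits, 1L) / nn)
  tab <- tab[tab$p_hyper < p_cut & tab$fold >= fold_min, ]
  out <- data.table::data.table(
    kmer = tab$canon, k = k, pos_hits = tab$pos_hits,
    neg_hits = tab$neg_hits, p_hyper = tab$p_hyper, fold = tab$fold,
    offset = tab$offset)
  data.table::setorderv(out, c("p_hyper", "fold", "kmer"),
                        order = c(1L, -1L, 1L))
  out[]
}

empty_kmer_table <- function() {
  data.table::data.table(kmer = character(), k = integer(),
                         pos_hits = integer(), neg_hits = integer(),
                         p_hyper = numeric(), fold = numeric(),
                         offset = numeric())
}

#' Logistic distance weight for PWM construction
#'
#' Density ratio \code{f(d)/f(0)} of the logistic distribution with mean 0
#' and variance 13 (scale \code{sqrt(39)/pi}), so that a sequence whose
#' class match sits on the estimated event position gets weight 1 and
#' weight decays with match-to-event distance.
#'
#' @param d Distance in bases.
#' @return Weight in (0, 1].
#' @export
logistic_weight <- function(d) {
  s <- sqrt(39) / pi
  stats::dlogis(d, 0, s) / stats::dlogis(0, 0, s)
}

#' Build a weighted PWM from aligned sequence windows
#'
#' Each window is weighted by its binding event read count times the
#' logistic distance weight of its class-match-to-event distance
#' (\code{\link{logistic_weight}}). Weighted base frequencies per column
#' (pseudocount added; N bases are ignored) are converted to log2-odds
#' against a zero-order background. The PWM match threshold is 60% of the
#' maximum achievable score.
#'
#' @param windows Character vector of equal-width aligned sequences
#'   (may contain N padding).
#' @param strengths Event read counts per window (default 1).
#' @param match_dists Class-match-to-event distances per window (default 0).
#' @param background Length-4 A/C/G/T background frequencies.
#' @param pseudocount Per-base per-column pseudocount (default 0.375).
#' @return A \code{gem_pwm}: list with \code{mat} (4 x width log2-odds,
#'   rows A,C,G,T), \code{prob}, \code{width}, \code{max_score},
#'   \code{threshold} (= 0.6 * max_score), \code{background},
#'   \code{nsites}.
#' @export
build_weighted_pwm <- function(windows, strengths = 1, match_dists = 0,
                               background = rep(0.25, 4L),
                               pseudocount = 0.375) {
  n <- length(windows)
  if (n < 2L) stop("need at least 2 matched sequences to build a PWM")
  w <- unique(nchar(windows))
  stopifnot(length(w) == 1L)
  strengths <- rep_len(strengths, n)
  match_dists <- rep_len(match_dists, n)
  wt <- strengths * logistic_weight(match_dists)
  if (all(wt == 0)) stop("all sequence weights are zero")
  codes <- matrix(unlist(lapply(windows, codes_of), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  counts <- matrix(0, 4L, w)
  for (b in 1:4) counts[b, ] <- colSums((codes == b) * wt)
  counts <- counts + pseudocount
  prob <- sweep(counts, 2L, colSums(counts), "/")
  mat <- log2(prob / background)
  new_gem_pwm(mat, prob, background, nsites = n)
}

new_gem_pwm <- function(mat, prob, background, nsites = NA_real_,
                        p_hyper = NA_real_, name = NULL) {
  rownames(mat) <- rownames(prob) <- c("A", "C", "G", "T")
  ms <- sum(apply(mat, 2L, max))
  structure(list(mat = mat, prob = prob, width = ncol(mat),
                 max_score = ms, threshold = 0.6 * ms,
                 background = background, nsites = nsites,
                 p_hyper = p_hyper, name = name),
            class = "gem_pwm")
}

#' @export
print.gem_pwm <- function(x, ...) {
  cat("PWM ", pwm_consensus(x), " (width ", x$width,
      ", max score ", round(x$max_score, 2),
      ", threshold ", round(x$threshold, 2), ")\n", sep = "")
  if (!is.na(x$p_hyper)) cat("  hypergeometric p = ",
                             format(x$p_hyper, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Consensus string of a PWM
#' @param pwm A \code{gem_pwm}.
#' @return Character consensus (highest-probability base per column).
#' @export
pwm_consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$prob, 2L, which.max)], collapse = "")
}

# Reverse-complement log-odds matrix: swap A<->T, C<->G and reverse columns.
rc_mat <- function(mat) mat[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(mat))), drop = FALSE]

#' Scan a sequence with a PWM
#'
#' Both strands are scanned; all (possibly overlapping) positions scoring at
#' least the PWM threshold (60% of the maximum score) are reported. N bases
#' score 0 (background odds). A minus-strand match at start \code{pos}
#' covers the same forward-coordinate interval \code{[pos, pos + width)}.
#'
#' @param pwm A \code{gem_pwm}.
#' @param sequence A character sequence over A/C/G/T/N.
#' @param threshold Score cutoff; defaults to \code{pwm$threshold}.
#' @return data.table(\code{pos} (0-based start), \code{strand},
#'   \code{score}, \code{center} (0-based coordinate of the match middle)).
#' @export
scan_pwm <- function(pwm, sequence, threshold = NULL) {
  if (is.null(threshold)) threshold <- pwm$threshold
  codes <- codes_of(sequence)
  w <- pwm$width
  fw <- pwm_scores_cpp(codes, pwm$mat)
  rv <- pwm_scores_cpp(codes, rc_mat(pwm$mat))
  hf <- which(fw >= threshold)
  hr <- which(rv >= threshold)
  out <- data.table::data.table(
    pos = c(hf, hr) - 1L,
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    score = c(fw[hf], rv[hr]))
  out$center <- out$pos + (w - 1L) %/% 2L
  data.table::setorderv(out, c("pos", "strand"))
  out[]
}

# Count of sequences containing at least one PWM match at >= threshold.
pwm_hit_count <- function(pwm, seqs) {
  sum(vapply(seqs, function(s) {
    nrow(scan_pwm(pwm, s)) > 0L
  }, logical(1L)))
}

pwm_hyper_p <- function(pos_hits, neg_hits, np, nn) {
  K <- pos_hits + neg_hits
  stats::phyper(pos_hits - 1, K, np + nn - K, np, lower.tail = FALSE)
}

#' Trim a PWM to its most discriminative column sub-range
#'
#' Evaluates every contiguous column sub-range of width at least
#' \code{min_width}: each sub-PWM matches a sequence when some alignment
#' (either strand) scores at least 60% of the sub-PWM's maximum score, and
#' the sub-range with the most significant hypergeometric p-value between
#' positive and negative sequence hits is returned (ties broken toward the
#' widest, then leftmost, sub-range).
#'
#' @param pwm A \code{gem_pwm}.
#' @param pos,neg Character vectors of positive / negative sequences.
#' @param min_width Minimum retained width (default 5).
#' @return The trimmed \code{gem_pwm} with its \code{p_hyper} filled in.
#' @export
trim_pwm <- function(pwm, pos, neg, min_width = 5L) {
  w <- pwm$width
  if (w < min_width) stop("PWM narrower than min_width")
  fmat <- pwm$mat
  rmat <- rc_mat(fmat)
  bp <- best_subrange_scores_cpp(lapply(pos, codes_of), fmat, rmat)
  bn <- best_subrange_scores_cpp(lapply(neg, codes_of), fmat, rmat)
  colmax <- apply(fmat, 2L, max)
  cm <- c(0, cumsum(colmax))
  best <- NULL
  for (a in 1:w) for (b in a:w) {
    if (b - a + 1L < min_width) next
    thr <- 0.6 * (cm[b + 1L] - cm[a])
    idx <- (a - 1L) * w + b
    hp <- sum(bp[, idx] >= thr)
    hn <- sum(bn[, idx] >= thr)
    p <- pwm_hyper_p(hp, hn, length(pos), length(neg))
    width <- b - a + 1L
    if (is.null(best) || p < best$p ||
        (p == best$p && (width > best$width ||
                         (width == best$width && a < best$a)))) {
      best <- list(a = a, b = b, p = p, width = width, hp = hp)
    }
  }
  n_ranges <- sum(vapply(1:w, function(a) max(0L, w - max(a + min_width - 1L,
                                                          a) + 1L),
                         integer(1L)))
  sub <- new_gem_pwm(pwm$mat[, best$a:best$b, drop = FALSE],
                     pwm$prob[, best$a:best$b, drop = FALSE],
                     pwm$background, nsites = pwm$nsites,
                     p_hyper = best$p, name = pwm$name)
  sub$trim_range <- c(best$a, best$b)
  sub$pos_hits <- best$hp
  sub$n_ranges <- n_ranges
  sub
}

# Best single PWM match in a sequence over both strands (score, 0-based
# start, strand); ties toward the forward strand, then the leftmost start.
pwm_best_match <- function(pwm, sequence) {
  codes <- codes_of(sequence)
  fw <- pwm_scores_cpp(codes, pwm$mat)
  rv <- pwm_scores_cpp(codes, rc_mat(pwm$mat))
  if (length(fw) == 0L) return(NULL)
  bf <- which.max(fw); br <- which.max(rv)
  if (fw[bf] >= rv[br]) list(score = fw[bf], pos = bf - 1L, strand = "+")
  else list(score = rv[br], pos = br - 1L, strand = "-")
}

# Extract width-(2k+1) windows of `seqs[i]` centered at 0-based positions
# mc[i], N-padded at the edges; windows with fwd[i] FALSE are
# reverse-complemented (one batched call) so all windows share the class
# frame.
centered_windows <- function(seqs, mc, k, fwd) {
  n <- nchar(seqs)
  lo <- mc - k; hi <- mc + k
  pad_l <- pmax(0L, -lo); pad_r <- pmax(0L, hi - (n - 1L))
  core <- substr(seqs, pmax(1L, lo + 1L), pmin(n, hi + 1L))
  win <- paste0(strrep("N", pad_l), core, strrep("N", pad_r))
  if (any(!fwd)) win[!fwd] <- revcomp(win[!fwd])
  win
}

#' Grow a k-mer equivalence class from a seed and derive its PWM
#'
#' The class is seeded with the most enriched k-mer and its
#' Hamming-distance-1 neighbors from the enriched pool, then alternates:
#' (a) pool k-mers occurring in the \code{2k+1} bp windows around class
#' matches with a consistent alignment offset in at least one third of
#' their occurrences are admitted; (b) a distance- and strength-weighted
#' PWM is rebuilt from the matched positive windows and trimmed; (c) the
#' windows are re-extracted around the best PWM match per positive
#' sequence and step (a) repeats. Iteration stops when the trimmed PWM's
#' hypergeometric p-value no longer improves.
#'
#' @param seed Seed k-mer (character) or a row index into \code{pool};
#'   by convention the most enriched remaining k-mer.
#' @param pool Enriched k-mer table from \code{\link{find_enriched_kmers}}.
#' @param pos,neg Character vectors of positive / negative sequences.
#' @param strengths Event strengths parallel to \code{pos} (default 1).
#' @param center 1-based event base index in positive sequences (default
#'   middle).
#' @param max_rounds Cap on (a)/(b) alternations.
#' @return A \code{gem_class}: list with \code{seed}, \code{members}
#'   (data.table \code{kmer}, \code{pos_hits}, \code{offset} (expected
#'   event offset), \code{class_offset}, \code{orient}), \code{pwm}
#'   (trimmed \code{gem_pwm} or NULL when the class matches no positive
#'   sequence), \code{p_hyper}, \code{n_matched}.
#' @export
grow_kmer_class <- function(seed, pool, pos, neg, strengths = NULL,
                            center = NULL, max_rounds = 6L) {
  if (nrow(pool) == 0L) stop("empty enriched k-mer pool")
  if (is.character(seed)) seed <- canonical_kmer(seed)
  else seed <- pool$kmer[seed]
  k <- nchar(seed)
  if (is.null(strengths)) strengths <- rep(1, length(pos))
  if (is.null(center)) center <- (min(nchar(pos)) + 1L) %/% 2L
  background <- base_background(neg)
  # step 1: seed + Hamming-1 neighbors (either orientation)
  hm <- pmin(kmer_hamming(seed, pool$kmer), kmer_hamming(seed, revcomp(pool$kmer)))
  members <- pool[hm <= 1L, ]
  members$class_offset <- 0L
  members$orient <- ifelse(kmer_hamming(seed, members$kmer) <= 1L, "+", "-")
  win_info <- class_match_windows(members, pos, k, center)
  if (is.null(win_info))
    return(structure(list(seed = seed, members = members, pwm = NULL,
                          p_hyper = 1, n_matched = 0L), class = "gem_class"))
  members <- admit_kmers(members, pool, win_info$windows, k)
  best <- NULL
  for (round in seq_len(max_rounds)) {
    # the PWM is always built from class-matched sequences; PWM matches
    # below only guide k-mer admission
    win_info <- class_match_windows(members, pos, k, center)
    if (is.null(win_info)) break
    pwm <- build_weighted_pwm(win_info$windows,
                              strengths[win_info$seq_ids],
                              win_info$dists, background)
    pwm <- trim_pwm(pwm, pos, neg)
    if (!is.null(best) && pwm$p_hyper >= best$pwm$p_hyper) break
    best <- list(pwm = pwm, members = data.table::copy(members),
                 n_matched = length(win_info$seq_ids))
    pw <- pwm_match_windows(pwm, pos, k, center)
    if (is.null(pw)) break
    n_before <- nrow(members)
    members <- admit_kmers(members, pool, pw$windows, k)
    if (nrow(members) == n_before) break
  }
  if (is.null(best))
    return(structure(list(seed = seed, members = members, pwm = NULL,
                          p_hyper = 1, n_matched = 0L), class = "gem_class"))
  structure(list(seed = seed, members = best$members, pwm = best$pwm,
                 p_hyper = best$pwm$p_hyper, n_matched = best$n_matched),
            class = "gem_class")
}

#' @export
print.gem_class <- function(x, ...) {
  cat("k-mer equivalence class seeded by ", x$seed, ": ",
      nrow(x$members), " member(s), ", x$n_matched,
      " matched positive sequence(s)\n", sep = "")
  if (!is.null(x$pwm)) print(x$pwm)
  invisible(x)
}

# Windows (2k+1 bp, oriented to the class frame) around the best class
# match per positive sequence. The per-sequence match is the occurrence of
# the most enriched member present, leftmost on ties.
class_match_windows <- function(members, pos, k, center) {
  occ <- kmer_occurrences(pos, k)
  occ <- occ[occ$canon %in% members$kmer, ]
  if (nrow(occ) == 0L) return(NULL)
  occ$rank <- match(occ$canon, members$kmer)   # members ordered by enrichment
  data.table::setorderv(occ, c("seq_id", "rank", "s"))
  occ <- occ[!duplicated(occ$seq_id), ]
  # orientation of the occurrence relative to the class frame
  orient <- members$orient[occ$rank]
  fwd <- (occ$fwd & orient == "+") | (!occ$fwd & orient == "-")
  mc <- occ$s + (k - 1L) %/% 2L
  windows <- centered_windows(pos[occ$seq_id], mc, k, fwd)
  list(windows = windows, seq_ids = occ$seq_id,
       dists = mc - (center - 1L))
}

# Windows around the best PWM match (>= threshold) per positive sequence.
pwm_match_windows <- function(pwm, pos, k, center) {
  ids <- integer(0); mcs <- integer(0); fwd <- logical(0)
  for (i in seq_along(pos)) {
    m <- pwm_best_match(pwm, pos[i])
    if (is.null(m) || m$score < pwm$threshold) next
    ids <- c(ids, i)
    mcs <- c(mcs, m$pos + (pwm$width - 1L) %/% 2L)
    fwd <- c(fwd, m$strand == "+")
  }
  if (length(ids) == 0L) return(NULL)
  list(windows = centered_windows(pos[ids], mcs, k, fwd), seq_ids = ids,
       dists = mcs - (center - 1L))
}

# Admit pool k-mers that occur at a consistent offset (same window start
# and orientation in >= 1/3 of their occurrences across the aligned
# windows).
admit_kmers <- function(members, pool, windows, k) {
  cand <- pool[!pool$kmer %in% members$kmer, ]
  if (nrow(cand) == 0L) return(members)
  occ <- kmer_occurrences(windows, k)
  occ <- occ[occ$canon %in% cand$kmer, ]
  if (nrow(occ) == 0L) return(members)
  occ$key <- paste(occ$s, occ$fwd)
  for (km in unique(occ$canon)) {
    oc <- occ[occ$canon == km, ]
    tab <- sort(table(oc$key), decreasing = TRUE)
    if (tab[1L] * 3L >= nrow(oc)) {
      top <- strsplit(names(tab)[1L], " ")[[1L]]
      row <- cand[cand$kmer == km, ]
      row$class_offset <- as.integer(top[1L]) - k  # relative to seed start
      row$orient <- if (as.logical(top[2L])) "+" else "-"
      members <- rbind(members, row)
    }
  }
  members
}

# Mask PWM matches (>= threshold, both strands) with N.
mask_pwm <- function(seqs, pwm) {
  vapply(seqs, function(s) {
    m <- scan_pwm(pwm, s)
    if (nrow(m) == 0L) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (i in seq_len(nrow(m)))
      v[(m$pos[i] + 1L):min(length(v), m$pos[i] + pwm$width)] <- "N"
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Discover motifs from called binding events
#'
#' Runs the full k-mer enrichment and equivalence-class clustering for each
#' k in \code{k_range}, picks the k whose primary (trimmed) PWM is most
#' significantly enriched, then repeatedly masks the accepted PWM's
#' occurrences and removes its seed from the pool to search for secondary
#' motifs, until no class passes the significance gate. If a secondary
#' motif turns out more significant than the primary, discovery restarts
#' seeded from it.
#'
#' @param events Event table (needs \code{chrom}, \code{pos}; uses
#'   \code{strength} for PWM weighting when present).
#' @param genome A \code{DNAStringSet}.
#' @param k_range k values to scan (default 5:13).
#' @param max_motifs Cap on reported motifs.
#' @param flank Positive/negative window half-width (default 30 -> 61 bp).
#' @param p_gate Class acceptance gate on the trimmed PWM hypergeometric
#'   p-value (default 1e-3, the same gate as k-mer enrichment), applied
#'   after a Bonferroni adjustment for the trimming sub-ranges and k
#'   values searched — the trimmed p-value is a selected minimum, and an
#'   unadjusted gate lets overfit classes through on motif-free input.
#' @return List of \code{gem_class} objects ordered by significance
#'   (empty when nothing passes the gates).
#' @export
discover_motifs <- function(events, genome, k_range = 5:13, max_motifs = 5L,
                            flank = 30L, p_gate = 1e-3) {
  sets <- extract_sets(events, genome, flank = flank)
  if (nrow(sets$pos) < 50L)
    warning("only ", nrow(sets$pos), " usable events; motif discovery is ",
            "unreliable below 50")
  discover_motifs_sets(sets$pos$seq, sets$neg$seq,
                       strengths = sets$pos$strength,
                       center = sets$pos$center[1L],
                       k_range = k_range, max_motifs = max_motifs,
                       p_gate = p_gate)
}

# Sequence-level driver behind discover_motifs (also used directly by the
# simulator-based tests).
discover_motifs_sets <- function(pos, neg, strengths = NULL, center = NULL,
                                 k_range = 5:13, max_motifs = 5L,
                                 p_gate = 1e-3) {
  if (length(pos) < 2L || length(neg) == 0L) return(list())
  k_range <- k_range[k_range <= min(nchar(c(pos, neg)))]
  # choose k by the most significant primary PWM
  best_k <- NULL
  for (k in k_range) {
    enr <- find_enriched_kmers(pos, neg, k, center = center)
    if (nrow(enr) == 0L) next
    cl <- grow_kmer_class(1L, enr, pos, neg, strengths, center)
    if (is.null(cl$pwm)) next
    if (is.null(best_k) || cl$p_hyper < best_k$class$p_hyper)
      best_k <- list(k = k, class = cl, pool = enr)
  }
  if (is.null(best_k)) return(list())
  # acceptance is Bonferroni-adjusted for the selection performed: the
  # trimmed p-value is a minimum over the evaluated column sub-ranges and
  # the scanned k values
  sel <- function(cl) max(1L, cl$pwm$n_ranges %||% 1L) * length(k_range)
  if (best_k$class$p_hyper >= p_gate / sel(best_k$class)) return(list())
  k <- best_k$k
  primary <- best_k$class
  motifs <- list()
  restarts <- 0L
  repeat {
    motifs <- list(primary)
    used_seeds <- primary$seed
    pos_m <- mask_pwm(pos, primary$pwm)
    neg_m <- mask_pwm(neg, primary$pwm)
    restarted <- FALSE
    while (length(motifs) < max_motifs) {
      enr <- find_enriched_kmers(pos_m, neg_m, k, center = center)
      enr <- enr[!enr$kmer %in% used_seeds, ]
      if (nrow(enr) == 0L) break
      cl <- grow_kmer_class(1L, enr, pos_m, neg_m, strengths, center)
      if (is.null(cl$pwm) || cl$p_hyper >= p_gate / sel(cl)) break
      if (cl$p_hyper < primary$p_hyper && restarts < 2L) {
        # secondary beats primary: restart discovery seeded from it
        full_pool <- find_enriched_kmers(pos, neg, k, center = center)
        if (cl$seed %in% full_pool$kmer) {
          cand <- grow_kmer_class(cl$seed, full_pool, pos, neg,
                                  strengths, center)
          if (!is.null(cand$pwm) && cand$p_hyper < primary$p_hyper) {
            primary <- cand
            restarts <- restarts + 1L
            restarted <- TRUE
            break
          }
        }
      }
      motifs <- c(motifs, list(cl))
      used_seeds <- c(used_seeds, cl$seed)
      pos_m <- mask_pwm(pos_m, cl$pwm)
      neg_m <- mask_pwm(neg_m, cl$pwm)
    }
    if (!restarted) break
  }
  motifs[order(vapply(motifs, function(m) m$p_hyper, numeric(1L)))]
}

#' Write a text report of k-mer equivalence classes
#'
#' One block per class: the seed, the trimmed PWM consensus and p-value,
#' then one line per member k-mer with its class alignment offset,
#' orientation, expected event offset and positive-set hit count.
#'
#' @param classes List of \code{gem_class} objects.
#' @param path Output path.
#' @export
write_kmer_classes <- function(classes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    writeLines(sprintf("#class %d seed=%s p_hyper=%.4g consensus=%s", i,
                       cl$seed, cl$p_hyper,
                       if (is.null(cl$pwm)) "." else pwm_consensus(cl$pwm)),
               con)
    writeLines("kmer\tclass_offset\torient\tevent_offset\tpos_hits", con)
    m <- cl$members
    writeLines(sprintf("%s\t%d\t%s\t%.2f\t%d", m$kmer,
                       as.integer(m$class_offset), m$orient, m$offset,
                       as.integer(m$pos_hits)), con)
  }
  invisible(path)
}
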