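# helper alias (canonical_kmer is internal)
canonical_kmer_pub <- function(x) chipem:::canonical_kmer(x)

test_that("positive and negative windows sit where the arithmetic says", {
  set.seed(11)
  g <- Biostrings::DNAStringSet(c(chr1 = random_seqs(1, 5000)))
  ev <- data.frame(chrom = "chr1", pos = 1000L, strength = 5)
  sets <- extract_sets(ev, g)
  expect_equal(sets$pos$start, 970L)
  expect_equal(nchar(sets$pos$seq), 61L)
  expect_equal(sort(sets$neg$start), c(700L, 1300L) - 30L)
  # two events 300 bp apart: the negative between them overlaps a positive
  ev2 <- data.frame(chrom = "chr1", pos = c(1000L, 1300L), strength = 5)
  sets2 <- extract_sets(ev2, g)
  expect_false(any(sets2$neg$start %in% c(1270L, 970L)))
  width <- 61L
  for (i in seq_len(nrow(sets2$neg)))
    expect_false(any(sets2$neg$start[i] < sets2$pos$start + width &
                       sets2$pos$start < sets2$neg$start[i] + width))
})

test_that("no negative window overlaps a positive one across a simulated event set", {
  sim <- simulate_dataset(genome_length = 2e5, n_events = 100L,
                          reads_per_event = 10L, noise_frac = 0, seed = 12L)
  sets <- extract_sets(sim$events, sim$genome)
  width <- 61L
  for (i in seq_len(nrow(sets$neg)))
    expect_false(any(sets$neg$start[i] < sets$pos$start + width &
                       sets$pos$start < sets$neg$start[i] + width))
})

test_that("k-mer enrichment uses per-sequence hits, canonical forms, and the hypergeometric tail", {
  set.seed(21)
  neg <- random_seqs(100, 61)
  pos <- random_seqs(100, 61)
  # plant a 6-mer in 40 positives and 5 negatives (at varying positions)
  for (i in 1:40) substr(pos[i], 20 + (i %% 5), 25 + (i %% 5)) <- "ACGGTC"
  for (i in 1:5) substr(neg[i], 10, 15) <- "ACGGTC"
  enr <- find_enriched_kmers(pos, neg, 6)
  km <- enr[enr$kmer == canonical_kmer_pub("ACGGTC"), ]
  expect_equal(nrow(km), 1L)
  expect_gte(km$pos_hits, 40L)
  expect_equal(km$p_hyper,
               hyper_tail_oracle(km$pos_hits, km$pos_hits + km$neg_hits,
                                 200, 100),
               tolerance = 1e-9)
  expect_gte(km$fold, 3)
})

test_that("a k-mer present everywhere is not enriched and short sequences error", {
  pos <- rep("AAAAACGTAA", 30)
  neg <- rep("AAAAACGTAA", 30)
  enr <- find_enriched_kmers(pos, neg, 5)
  expect_equal(nrow(enr), 0L)
  expect_error(find_enriched_kmers(pos, neg, 11), "exceeds")
})

test_that("a sequence and its reverse complement carry the same canonical k-mers", {
  # ACGTT's reverse complement is AACGT: one canonical 5-mer
  occ <- chipem:::kmer_occurrences(c("ACGTT", "AACGT"), 5)
  expect_equal(unique(occ$canon), "AACGT")
  expect_equal(nrow(occ), 2L)
})

test_that("the logistic distance weight matches its closed form", {
  expect_equal(logistic_weight(0), 1)
  s <- sqrt(39) / pi
  expect_equal(logistic_weight(5),
               4 * exp(-5 / s) / (1 + exp(-5 / s))^2, tolerance = 1e-12)
  expect_equal(logistic_weight(5), 0.277, tolerance = 1e-3)
  expect_equal(logistic_weight(-3), logistic_weight(3))
})

test_that("weighted PWM columns reflect weighted base frequencies", {
  pwm <- build_weighted_pwm(c("AA", "AC"), strengths = c(1, 1))
  expect_equal(unname(which.max(pwm$mat[, 1])), 1L)
  expect_equal(unname(pwm$mat["A", 2]), unname(pwm$mat["C", 2]),
               tolerance = 1e-12)
  expect_equal(pwm$threshold / pwm$max_score, 0.6, tolerance = 1e-12)
  expect_error(build_weighted_pwm("AA"), "at least 2")
  expect_error(build_weighted_pwm(c("AA", "AC"), strengths = c(0, 0)),
               "zero")
})

test_that("PWM scanning equals naive per-position rescoring on random sequence", {
  set.seed(31)
  prob <- consensus_to_pwm("GGGTGGGA", major = 0.85)
  pwm <- pwm_from_prob(prob)
  seqc <- random_seqs(1, 10000, alphabet = c("A", "C", "G", "T", "N"))
  got <- scan_pwm(pwm, seqc)
  want <- naive_scan_oracle(pwm, seqc)
  got <- got[order(got$pos, got$strand), ]
  want <- want[order(want$pos, want$strand), ]
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$pos, want$pos)
  expect_equal(got$strand, want$strand)
  expect_equal(got$score, want$score, tolerance = 1e-9)
  # the consensus sequence scores the maximum
  hit <- scan_pwm(pwm, "GGGTGGGA")
  expect_equal(max(hit$score), pwm$max_score, tolerance = 1e-9)
})

test_that("trimming picks the most discriminative sub-range and is idempotent", {
  set.seed(41)
  core <- consensus_to_pwm("ACGTACG", major = 0.95)
  # weakly (and wrongly) informative flanks: they raise the threshold
  # without matching the planted context, so including them hurts
  flank <- matrix(c(0.7, 0.1, 0.1, 0.1), 4, 3)
  prob <- cbind(flank, core, flank)  # 13 columns, informative middle
  pwm <- pwm_from_prob(prob)
  pos <- paste0(random_seqs(60, 10), "ACGTACG", random_seqs(60, 10))
  neg <- random_seqs(80, 27)
  tr <- trim_pwm(pwm, pos, neg)
  expect_lte(tr$width, pwm$width)
  expect_lte(tr$width, 9)           # background flanks excluded
  expect_gte(tr$width, 5)
  # exhaustive oracle over all sub-ranges of width >= 5
  best_p <- Inf
  for (a in 1:13) for (b in a:13) {
    if (b - a + 1 < 5) next
    sub <- pwm_from_prob(prob[, a:b, drop = FALSE])
    hp <- sum(vapply(pos, function(s) nrow(scan_pwm(sub, s)) > 0, logical(1)))
    hn <- sum(vapply(neg, function(s) nrow(scan_pwm(sub, s)) > 0, logical(1)))
    p <- hyper_tail_oracle(hp, hp + hn, length(pos) + length(neg),
                           length(pos))
    if (p < best_p) best_p <- p
  }
  expect_equal(tr$p_hyper, best_p, tolerance = 1e-6)
  tr2 <- trim_pwm(tr, pos, neg)
  expect_equal(tr2$width, tr$width)
  expect_equal(tr2$mat, tr$mat)
})

test_that("class seeding admits Hamming-1 neighbors and offset-consistency gates members", {
  pool <- data.table::data.table(
    kmer = c("CCCCACCC", "CCCCTCCC", "AAAATTTT"),
    k = 8L, pos_hits = c(30L, 10L, 8L), neg_hits = c(1L, 1L, 1L),
    p_hyper = c(1e-9, 1e-5, 1e-4), fold = c(10, 5, 4),
    offset = c(3, 3, 0))
  set.seed(51)
  pos <- vapply(1:40, function(i) {
    s <- random_seqs(1, 61)
    substr(s, 28, 35) <- if (i <= 30) "GGGTGGGG" else "GGGAGGGG"
    s
  }, "")
  neg <- random_seqs(40, 61)
  cl <- grow_kmer_class("CCCCACCC", pool, pos, neg)
  expect_true(all(c("CCCCACCC", "CCCCTCCC") %in% cl$members$kmer))
  expect_false("AAAATTTT" %in% cl$members$kmer)
})

test_that("candidate k-mers need a consistent alignment offset in a third of occurrences", {
  # candidate appears at scattered offsets in 9 windows: 2/9 at the modal
  # offset is below 1/3 -> rejected; 4/9 at one offset -> admitted
  members <- data.table::data.table(
    kmer = "ACGTACGT", k = 8L, pos_hits = 10L, neg_hits = 0L,
    p_hyper = 1e-8, fold = 10, offset = 0, class_offset = 0L, orient = "+")
  cand <- data.table::data.table(
    kmer = "AACCGGTT", k = 8L, pos_hits = 5L, neg_hits = 0L,
    p_hyper = 1e-4, fold = 5, offset = 0)
  pool <- rbind(members[, names(cand), with = FALSE], cand)
  win_at <- function(offsets) vapply(offsets, function(o) {
    s <- paste(rep("A", 17), collapse = "")
    substr(s, o + 1, o + 8) <- "AACCGGTT"
    s
  }, "")
  scattered <- win_at(c(1, 2, 3, 4, 5, 6, 7, 1, 2))   # max 2/9 < 1/3
  rej <- chipem:::admit_kmers(members, pool, scattered, 8L)
  expect_false("AACCGGTT" %in% rej$kmer[-1])
  consistent <- win_at(c(3, 3, 3, 3, 5, 6, 7, 1, 2))  # 4/9 >= 1/3
  acc <- chipem:::admit_kmers(members, pool, consistent, 8L)
  expect_true("AACCGGTT" %in% acc$kmer)
})

test_that("a planted motif is recovered as a PWM correlated with the truth", {
  set.seed(61)
  truth <- consensus_to_pwm("TTACGTCAAG", major = 0.9)
  pos <- vapply(1:80, function(i) {
    s <- random_seqs(1, 61)
    inst <- paste(apply(truth, 2, function(p)
      sample(c("A", "C", "G", "T"), 1, prob = p)), collapse = "")
    substr(s, 26, 35) <- inst
    s
  }, "")
  neg <- random_seqs(120, 61)
  motifs <- chipem:::discover_motifs_sets(pos, neg, center = 31)
  expect_gte(length(motifs), 1L)
  pwm <- motifs[[1]]$pwm
  expect_gt(pwm_truth_cor(pwm, truth), 0.9)
})

test_that("two planted motifs are both discovered, ordered by significance", {
  set.seed(71)
  pos <- vapply(1:100, function(i) {
    s <- random_seqs(1, 61)
    if (i %% 2 == 0) substr(s, 26, 35) <- "TTACGTCAAG"
    else substr(s, 26, 34) <- "GGGCGGGGC"
    s
  }, "")
  neg <- random_seqs(150, 61)
  motifs <- chipem:::discover_motifs_sets(pos, neg, center = 31)
  expect_gte(length(motifs), 2L)
  ps <- vapply(motifs, function(m) m$p_hyper, numeric(1))
  expect_true(!is.unsorted(ps))
  cons <- vapply(motifs[1:2], function(m) pwm_consensus(m$pwm), "")
  hit1 <- any(vapply(cons, consensus_matches, logical(1),
                     truth_cons = "TTACGTCAAG"))
  hit2 <- any(vapply(cons, consensus_matches, logical(1),
                     truth_cons = "GGGCGGGGC"))
  expect_true(hit1 && hit2)
})

test_that("motif-free sequences yield no motif at the enrichment gates", {
  set.seed(81)
  pos <- random_seqs(60, 61)
  neg <- random_seqs(90, 61)
  motifs <- chipem:::discover_motifs_sets(pos, neg, center = 31)
  expect_length(motifs, 0L)
})

test_that("discovery on reverse-complemented sequences mirrors the motif with equal significance", {
  set.seed(91)
  pos <- vapply(1:80, function(i) {
    s <- random_seqs(1, 61)
    substr(s, 26, 35) <- "TTACGTCAAG"
    s
  }, "")
  neg <- random_seqs(120, 61)
  m1 <- chipem:::discover_motifs_sets(pos, neg, center = 31)
  m2 <- chipem:::discover_motifs_sets(revcomp(pos), revcomp(neg), center = 31)
  expect_gte(length(m1), 1L)
  expect_gte(length(m2), 1L)
  expect_equal(m2[[1]]$p_hyper, m1[[1]]$p_hyper, tolerance = 1e-9)
  c1 <- pwm_consensus(m1[[1]]$pwm)
  c2 <- pwm_consensus(m2[[1]]$pwm)
  expect_true(c2 %in% c(c1, rc_oracle(c1)))
})

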