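chrlen <- c(chr1 = 100000L)

test_that("region segmentation splits at >500 bp gaps and drops sparse groups", {
  reads <- data.table::data.table(chrom = "chr1",
                                  pos5 = c(10L, 11L, 12L, 13L, 14L, 15L),
                                  strand = "+")
  regs <- segment_regions(reads, chrlen)
  expect_length(regs, 1L)
  expect_equal(nrow(regs[[1]]$reads), 6L)
  expect_equal(regs[[1]]$start, 0L)        # clipped at the contig start
  expect_equal(regs[[1]]$end, 15L + 501L)
  # a lone read across a 505 bp gap forms its own group and is dropped
  reads2 <- rbind(reads, data.table::data.table(chrom = "chr1", pos5 = 520L,
                                                strand = "+"))
  regs2 <- segment_regions(reads2, chrlen)
  expect_length(regs2, 1L)
  expect_equal(nrow(regs2[[1]]$reads), 6L)
})

test_that("segmentation partitions retained reads with no internal gap above the threshold", {
  set.seed(7)
  reads <- data.table::data.table(
    chrom = "chr1", pos5 = sort(sample.int(50000L, 1000L, replace = TRUE)),
    strand = sample(c("+", "-"), 1000L, replace = TRUE))
  regs <- segment_regions(reads, chrlen)
  got <- sort(unlist(lapply(regs, function(r) r$reads$pos5)))
  # brute-force oracle: group by scanning gaps, keep groups of >= 6
  p <- sort(reads$pos5)
  grp <- cumsum(c(0L, diff(p) > 500L))
  keep <- unlist(lapply(split(p, grp), function(g)
    if (length(g) >= 6L) g else NULL))
  expect_equal(got, unname(sort(keep)))
  for (r in regs)
    expect_true(all(diff(sort(r$reads$pos5)) <= 500L))
})

test_that("M-step matches the closed form max(0, N - alpha_s + alpha) with elimination", {
  expect_equal(m_step_update(10, 3)$pi, 1)
  up <- m_step_update(c(10, 2), 5)
  expect_equal(up$pi, 1)
  expect_equal(up$active, c(TRUE, FALSE))
  # hand evaluation: u = (7, 5, 1)
  up3 <- m_step_update(c(10, 6, 4), 3, c(0, 2, 0))
  expect_equal(up3$pi, c(7, 5, 1) / 13)
  # all components driven to zero -> empty survivor set
  expect_length(m_step_update(c(1, 2), 5)$pi, 0L)
  expect_error(m_step_update(10, 3, alpha = 4), "strictly below")
})

test_that("degenerate point-mass likelihood yields one event holding every read", {
  d <- read_dist(0L, 1)
  r <- manual_region(rep(50L, 10L), rep("+", 10L), 0L, 200L)
  fit <- em_fit(r, d, alpha_s = 1, refine_bp = 0L)
  expect_equal(nrow(fit$events), 1L)
  expect_equal(fit$events$pos, 50L)
  expect_equal(fit$events$strength, 10, tolerance = 1e-9)
})

test_that("two planted events 32 bp apart are each recovered within 2 bp", {
  sim <- simulate_dataset(genome_length = 20000L, n_events = 2L,
                          reads_per_event = 500L, noise_frac = 0,
                          seed = 4L, event_positions = c(5000L, 5032L))
  res <- call_events(sim$reads, c(chr1 = 20000L),
                     default_distribution("chipseq"))
  expect_equal(nrow(res$events), 2L)
  expect_lte(abs(res$events$pos[1] - 5000L), 2L)
  expect_lte(abs(res$events$pos[2] - 5032L), 2L)
})

test_that("a positional prior decides between likelihood-tied positions", {
  # a symmetric pile: plus reads at p-37, minus reads at (p+2)+37 make
  # positions p and p+2 exactly equivalent by likelihood; the prior at p
  # must pick p
  d <- default_distribution("chipseq")
  p <- 600L
  r <- manual_region(c(rep(p - 37L, 10L), rep(p + 39L, 10L)),
                     rep(c("+", "-"), each = 10L), 0L, 1200L)
  prior <- numeric(1200L)
  prior[p + 1L] <- 0.5 * sqrt(20)
  fit <- em_fit(r, d, prior = prior, alpha_s = sqrt(20))
  expect_equal(fit$events$pos, p)
  # and without the prior the same pile resolves deterministically too
  fit0 <- em_fit(r, d)
  expect_equal(nrow(fit0$events), 1L)
})

test_that("an event without k-mer support can survive on read evidence alone", {
  sim <- simulate_dataset(genome_length = 20000L, n_events = 1L,
                          reads_per_event = 200L, noise_frac = 0, seed = 9L)
  regs <- segment_regions(sim$reads, c(chr1 = 20000L))
  prior <- numeric(regs[[1]]$end - regs[[1]]$start)  # alpha_m = 0 everywhere
  fit <- em_fit(regs[[1]], default_distribution("chipseq"), prior = prior)
  expect_equal(nrow(fit$events), 1L)
  expect_lte(abs(fit$events$pos - sim$events$pos), 2L)
})

test_that("penalized objective is non-decreasing against the restructured model", {
  for (seed in 1:5) {
    sim <- simulate_dataset(genome_length = 30000L, n_events = 3L,
                            reads_per_event = 120L, noise_frac = 0.2,
                            seed = seed)
    regs <- segment_regions(sim$reads, c(chr1 = 30000L))
    for (r in regs) {
      fit <- em_fit(r, default_distribution("chipseq"))
      tr <- fit$state$trace
      if (is.null(tr)) next
      fixed <- tr$restructured == 0
      expect_true(all(tr$objective[fixed] >=
                        tr$objective_prev_restricted[fixed] - 1e-9))
    }
  }
})

test_that("effective counts conserve the reads explained by surviving components", {
  sim <- simulate_dataset(genome_length = 20000L, n_events = 2L,
                          reads_per_event = 150L, noise_frac = 0.1, seed = 2L)
  regs <- segment_regions(sim$reads, c(chr1 = 20000L))
  fit <- em_fit(regs[[1]], default_distribution("chipseq"))
  expect_equal(sum(fit$state$N_eff), nrow(fit$state$gamma), tolerance = 1e-6)
  expect_equal(unname(rowSums(fit$state$gamma)),
               rep(1, nrow(fit$state$gamma)), tolerance = 1e-9)
  expect_equal(sum(fit$state$pi), 1, tolerance = 1e-12)
})

test_that("with the sparse prior off, a lone event is recovered by plain ML", {
  d <- default_distribution("chipseq")
  # reads exactly at the distribution mode offset
  r <- manual_region(rep(1000L - 37L, 20L), rep("+", 20L), 0L, 2000L)
  fit <- em_fit(r, d, alpha_s = 0, refine_bp = 0L, anneal_iters = 0L)
  expect_equal(fit$state$positions[which.max(fit$state$N_eff)], 1000L)
})

test_that("binomial significance against a scaled control matches tail oracles", {
  genome_size <- 1e6
  ev <- data.table::data.table(chrom = "chr1", pos = 5000L, strength = 8)
  chip <- data.table::data.table(chrom = "chr1",
                                 pos5 = sample.int(1e6, 1000L) - 1L,
                                 strand = "+")
  # control with exactly 8 reads inside the 201 bp event window
  ctrl <- data.table::data.table(
    chrom = "chr1", pos5 = c(rep(5000L, 8L), sample.int(5e5, 992L) + 4e5),
    strand = "+")
  out <- test_significance(ev, chip, ctrl, genome_size)
  # scale = 1000/1000; n = 8 + 8; p = P(Bin(16, .5) >= 8)
  expect_equal(out$p_value, binom_tail_oracle(8, 16, 0.5), tolerance = 1e-9)
  expect_equal(out$p_value, 0.598, tolerance = 1e-3)
  expect_equal(out$fold, 8 / (8 + 1), tolerance = 1e-9)

  # a strong event over a weak matched-depth control is deeply significant
  ev2 <- data.table::data.table(chrom = "chr1", pos = 9e5, strength = 50)
  ctrl3 <- data.table::data.table(
    chrom = "chr1", pos5 = c(9e5, 9e5, sample.int(4e5, 998L) - 1L),
    strand = "+")
  out3 <- test_significance(ev2, chip, ctrl3, genome_size)
  expect_lt(out3$p_value, 1e-9)
})

test_that("without a control the dynamic Poisson tail is used", {
  # 201 reads uniform over 201 kb -> genome rate 0.001/bp; local windows
  # hold ~1 read each, so lambda for a 201 bp window is ~0.201; engineer
  # lambda = 1 by putting 5000 reads in 1 Mb (rate 0.005/bp -> 1.005/window)
  genome_size <- 1005000
  set.seed(1)
  chip <- data.table::data.table(
    chrom = "chr1", pos5 = sample.int(genome_size, 5000L) - 1L, strand = "+")
  ev <- data.table::data.table(chrom = "chr1", pos = 500000L, strength = 1)
  out <- test_significance(ev, chip, NULL, genome_size)
  lam <- max(5000 / genome_size,
             sum(abs(chip$pos5 - 5e5) <= 2500) / 5001,
             sum(abs(chip$pos5 - 5e5) <= 5000) / 10001) * 201
  expect_equal(out$p_value, pois_tail_oracle(1, lam), tolerance = 1e-9)
  expect_equal(out$fold, Inf)
})

test_that("BH correction reproduces the step-up q-values", {
  expect_equal(bh_correct(0.01), 0.01)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_correct(numeric(0)), numeric(0))
  set.seed(5)
  p <- runif(50)
  o <- order(p)
  expect_equal(bh_correct(p)[o], bh_correct(p[o]))
  expect_true(all(bh_correct(p) >= p))
})
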