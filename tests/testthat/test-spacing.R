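ev_tab <- function(pos, chrom = "chr1")
  data.table::data.table(chrom = chrom, pos = as.integer(pos), strength = 1)

test_that("offsets are signed relative to oriented anchors", {
  # unoriented anchors count in the plus frame
  pr <- spacing_histogram(ev_tab(994), ev_tab(1000))
  expect_equal(pr$count[pr$offset == -6], 1L)
  expect_equal(sum(pr$count), 1L)
  # a minus-oriented anchor mirrors the offset: plant the anchor motif
  # reverse-complemented so orientation comes out "-"
  set.seed(7)
  gs <- random_seqs(1, 3000)
  motif <- "TTACGTCAAG"
  substr(gs, 996, 1005) <- rc_oracle(motif)   # centered at 0-based 1000
  genome <- Biostrings::DNAStringSet(c(chr1 = gs))
  pwmB <- pwm_from_prob(consensus_to_pwm(motif))
  pr2 <- spacing_histogram(ev_tab(1006), ev_tab(1000), pwm_B = pwmB,
                           genome = genome)
  expect_equal(pr2$count[pr2$offset == -6], 1L)
})

test_that("planted pairs at +25 dominate the histogram and pass the Poisson test", {
  sp <- simulate_spacing_pair(d = 25L, n_pairs = 150L, seed = 5L)
  pwmB <- pwm_from_prob(consensus_to_pwm("GGGTGGGGAG"))
  pr <- spacing_histogram(sp$events_A, sp$events_B, pwm_B = pwmB,
                          genome = sp$genome)
  expect_equal(pr$offset[which.max(pr$count)], 25L)
  pr <- test_spacing(pr)
  expect_equal(pr$offset[which.min(pr$p_corrected)], 25L)
  expect_lt(pr$p_corrected[pr$offset == 25L], 1e-8)
})

test_that("Poisson offset test matches the tail oracle with Bonferroni scaling", {
  pr <- structure(list(offset = -100:100, count = integer(201),
                       n_anchor = 10L, flank_count = 804L,
                       flank_positions = 402L, lambda = 2),
                  class = "spacing_profile")
  pr$count[pr$offset == 10] <- 20L
  out <- test_spacing(pr, n_tests_total = 1L)
  expect_equal(out$p_raw[out$offset == 10], pois_tail_oracle(20, 2),
               tolerance = 1e-12)
  expect_equal(out$p_corrected[out$offset == 10],
               min(1, pois_tail_oracle(20, 2) * 201), tolerance = 1e-12)
  # zero counts can never be significant
  expect_true(all(out$p_raw[out$count == 0] == 1))
  # zero flank rate with nonzero counts falls back to the floored rate
  pr$flank_count <- 0L; pr$lambda <- 0
  out2 <- test_spacing(pr)
  expect_equal(out2$p_raw[out2$offset == 10],
               pois_tail_oracle(20, 1 / 402), tolerance = 1e-12)
})

test_that("spatial resolution centers offsets before averaging", {
  ev <- ev_tab(c(103, 205, 307))
  mot <- data.frame(chrom = "chr1", center = c(100, 200, 300))
  out <- spatial_resolution(ev, mot)
  expect_equal(sort(out$offsets), c(3, 5, 7))
  expect_equal(out$resolution, mean(abs(c(3, 5, 7) - 5)))
  # constant bias vanishes under centering
  out2 <- spatial_resolution(ev_tab(c(110, 210, 310)), mot)
  expect_equal(out2$resolution, 0)
  expect_error(spatial_resolution(ev_tab(5000), mot), "no event")
})

test_that("resolution approximates the noise scale of perturbed calls", {
  set.seed(33)
  truth <- seq(1000, 99000, by = 1000)
  lap <- function(n, b) { u <- runif(n) - 0.5; -b * sign(u) * log(1 - 2 * abs(u)) }
  noise <- lap(length(truth), 2)
  ev <- ev_tab(round(truth + noise))
  out <- spatial_resolution(ev, data.frame(chrom = "chr1", center = truth))
  expect_equal(out$resolution, mean(abs(noise - mean(noise))),
               tolerance = 0.35)
})

test_that("snapping moves events to the nearest motif middle within 50 bp inclusive", {
  set.seed(17)
  gs <- random_seqs(1, 4000)
  motif <- "TTACGTCAAG"
  for (start in c(960, 1011, 2000)) substr(gs, start, start + 9) <- motif
  genome <- Biostrings::DNAStringSet(c(chr1 = gs))
  pwm <- pwm_from_prob(consensus_to_pwm(motif))
  # centers (0-based) at start-1+4: 963, 1014, 2003
  ev <- ev_tab(c(1004, 2053, 3500))
  out <- snap_to_motif(ev, pwm, genome)
  expect_equal(out$pos[1], 1014L)     # 10 bp beats 41 bp
  expect_equal(out$pos[2], 2003L)     # exactly 50 bp away: inclusive
  expect_equal(out$pos[3], 3500L)     # nothing within range: unchanged
})

test_that("spacing profiles are invariant under genome reflection with strand swap", {
  sp <- simulate_spacing_pair(d = 25L, n_pairs = 60L, n_background = 40L,
                              seed = 9L)
  pwmB <- pwm_from_prob(consensus_to_pwm("GGGTGGGGAG"))
  pr <- test_spacing(spacing_histogram(sp$events_A, sp$events_B,
                                       pwm_B = pwmB, genome = sp$genome))
  G <- sum(Biostrings::width(sp$genome))
  rc_genome <- Biostrings::reverseComplement(sp$genome)
  names(rc_genome) <- names(sp$genome)
  flip <- function(ev) {
    out <- data.table::copy(ev); out$pos <- G - 1L - out$pos
    data.table::setorderv(out, "pos"); out
  }
  pr2 <- test_spacing(spacing_histogram(flip(sp$events_A),
                                        flip(sp$events_B),
                                        pwm_B = pwmB, genome = rc_genome))
  expect_equal(pr2$count, pr$count)
  expect_equal(pr2$lambda, pr$lambda)
})

test_that("an empty anchor set is an error and the pair summary reports the best offset", {
  expect_error(spacing_histogram(ev_tab(1), ev_tab(integer(0))), "empty")
  sp <- simulate_spacing_pair(d = -10L, n_pairs = 80L, seed = 2L)
  pr <- test_spacing(spacing_histogram(sp$events_A, sp$events_B))
  sm <- spacing_summary(list(A_vs_B = pr))
  expect_equal(sm$best_abs_offset, 10)
})
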