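## Synthetic ChIP data with planted ground truth: the test bed for every
## other module.

#' Turn a consensus string into a PWM probability matrix
#'
#' @param consensus Character string over A/C/G/T.
#' @param major Probability of the consensus base per column (default 0.9;
#'   the remainder is split evenly over the other bases).
#' @return A 4 x width probability matrix (rows A,C,G,T).
#' @export
consensus_to_pwm <- function(consensus, major = 0.9) {
  v <- codes_of(consensus)
  stopifnot(all(v <= 4L))
  w <- length(v)
  prob <- matrix((1 - major) / 3, 4L, w)
  prob[cbind(v, seq_len(w))] <- major
  rownames(prob) <- c("A", "C", "G", "T")
  prob
}

as_prob_matrix <- function(pwm) {
  if (inherits(pwm, "gem_pwm")) pwm$prob
  else if (is.character(pwm)) consensus_to_pwm(pwm)
  else pwm
}

sample_motif_instance <- function(prob) {
  paste(apply(prob, 2L, function(p)
    sample(c("A", "C", "G", "T"), 1L, prob = p)), collapse = "")
}

random_genome <- function(length, base_freq = rep(0.25, 4L)) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = base_freq), collapse = "")
}

# Uniform event placement with minimum separation and edge clearance;
# offending draws are resampled, error after `max_tries` failures.
place_events <- function(n, genome_length, clearance, min_sep = 10L,
                         max_tries = 1000L) {
  if (n == 0L) return(integer(0))
  lo <- clearance; hi <- genome_length - clearance - 1L
  stopifnot(hi > lo)
  pos <- sort(sample(lo:hi, n))
  tries <- 0L
  repeat {
    bad <- which(diff(pos) < min_sep)
    if (length(bad) == 0L) return(pos)
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " events at >= ", min_sep,
           " bp separation after ", max_tries, " tries")
    pos[bad + 1L] <- sample(lo:hi, length(bad))
    pos <- sort(pos)
  }
}

#' Simulate a ChIP experiment with planted binding events
#'
#' A background genome is drawn from a zero-order base model; motif
#' instances sampled from the PWM are planted centered on the event
#' positions (random orientation). Each event independently generates
#' reads: a fair coin picks the strand, and the 5' offset from the event
#' is sampled from the given read spatial distribution (mirrored for the
#' minus strand). Uniformly placed noise reads are added so that they make
#' up \code{noise_frac} of the ChIP sample, and a uniform control of
#' matched depth is generated. Everything is reproducible from
#' \code{seed}.
#'
#' @param genome_length Genome length in bp (one contig).
#' @param n_events Number of planted events.
#' @param pwm PWM probability matrix, \code{gem_pwm}, or consensus string
#'   (via \code{\link{consensus_to_pwm}}); \code{NULL} plants no motif.
#' @param strength_median,strength_sigma Log-normal event strength law
#'   (median reads per event and log-sd).
#' @param reads_per_event Fixed read count per event, overriding the
#'   strength law when non-NULL.
#' @param noise_frac Fraction of ChIP reads that are uniform noise.
#' @param dist Read spatial distribution (default ChIP-Seq shape).
#' @param seed Integer seed.
#' @param event_positions Optional fixed event positions (0-based),
#'   overriding random placement.
#' @param chrom Contig name.
#' @param min_sep Minimum event separation (bp).
#' @param base_freq Zero-order background base frequencies.
#' @return A list (class \code{sim_truth}): \code{genome}
#'   (\code{DNAStringSet}), \code{events} (chrom, pos, strength, motif,
#'   strand), \code{reads}, \code{control}, \code{dist}, \code{params}.
#' @export
simulate_dataset <- function(genome_length = 5e5, n_events = 50L,
                             pwm = NULL, strength_median = 100,
                             strength_sigma = 0.5, reads_per_event = NULL,
                             noise_frac = 0.3,
                             dist = default_distribution("chipseq"),
                             seed = 1L, event_positions = NULL,
                             chrom = "chr1", min_sep = 10L,
                             base_freq = rep(0.25, 4L)) {
  set.seed(seed)
  prob <- if (is.null(pwm)) NULL else as_prob_matrix(pwm)
  w <- if (is.null(prob)) 0L else ncol(prob)
  clearance <- dist$W + w
  gseq <- random_genome(genome_length, base_freq)
  if (is.null(event_positions)) {
    pos <- place_events(n_events, genome_length, clearance, min_sep)
  } else {
    pos <- sort(as.integer(event_positions))
    n_events <- length(pos)
  }
  strength <- if (!is.null(reads_per_event)) rep(reads_per_event, n_events)
  else stats::rlnorm(n_events, log(strength_median), strength_sigma)
  motif <- rep(NA_character_, n_events)
  mstrand <- rep(NA_character_, n_events)
  if (!is.null(prob) && n_events > 0L) {
    gvec <- strsplit(gseq, "", fixed = TRUE)[[1L]]
    for (i in seq_len(n_events)) {
      inst <- sample_motif_instance(prob)
      mstrand[i] <- sample(c("+", "-"), 1L)
      planted <- if (mstrand[i] == "+") inst else revcomp(inst)
      start <- pos[i] - (w - 1L) %/% 2L
      gvec[(start + 1L):(start + w)] <- strsplit(planted, "")[[1L]]
      motif[i] <- planted
    }
    gseq <- paste(gvec, collapse = "")
  }
  reads <- simulate_event_reads(pos, round(strength), dist, chrom,
                                genome_length)
  n_signal <- nrow(reads)
  n_noise <- round(noise_frac / (1 - noise_frac) * n_signal)
  noise <- uniform_reads(n_noise, genome_length, chrom)
  reads <- rbind(reads, noise)
  data.table::setorderv(reads, c("chrom", "pos5"))
  control <- uniform_reads(nrow(reads), genome_length, chrom)
  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, chrom))
  structure(list(
    genome = genome,
    events = data.table::data.table(chrom = chrom, pos = pos,
                                    strength = strength, motif = motif,
                                    strand = mstrand),
    reads = reads, control = control, dist = dist,
    params = list(genome_length = genome_length, n_events = n_events,
                  strength_median = strength_median,
                  strength_sigma = strength_sigma,
                  reads_per_event = reads_per_event,
                  noise_frac = noise_frac, seed = seed, chrom = chrom,
                  min_sep = min_sep, base_freq = base_freq)),
    class = "sim_truth")
}

simulate_event_reads <- function(pos, counts, dist, chrom, genome_length) {
  total <- sum(counts)
  if (total == 0L)
    return(data.table::data.table(chrom = character(), pos5 = integer(),
                                  strand = character()))
  ev <- rep(pos, counts)
  strand <- sample(c("+", "-"), total, replace = TRUE)
  off <- sample(dist$offset, total, replace = TRUE, prob = dist$prob)
  pos5 <- ifelse(strand == "+", ev + off, ev - off)
  pos5 <- pmin(pmax(pos5, 0L), genome_length - 1L)
  data.table::data.table(chrom = chrom, pos5 = as.integer(pos5),
                         strand = strand)
}

uniform_reads <- function(n, genome_length, chrom) {
  if (n == 0L)
    return(data.table::data.table(chrom = character(), pos5 = integer(),
                                  strand = character()))
  dt <- data.table::data.table(
    chrom = chrom,
    pos5 = sample.int(genome_length, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE))
  data.table::setorderv(dt, c("chrom", "pos5"))
  dt
}

#' Write a simulated dataset to disk
#'
#' Emits the genome FASTA, ChIP and control reads as BED6 (36 bp
#' alignments whose 5' ends reproduce the simulated positions), the truth
#' table and a config echo; all paths share \code{prefix}.
#'
#' @param sim A \code{sim_truth} from \code{\link{simulate_dataset}}.
#' @param prefix Output path prefix.
#' @return Named vector of written paths.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(genome = paste0(prefix, "_genome.fa"),
             reads = paste0(prefix, "_reads.bed"),
             control = paste0(prefix, "_control.bed"),
             truth = paste0(prefix, "_truth.txt"),
             config = paste0(prefix, "_config.txt"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_reads_bed(sim$reads, paths["reads"])
  write_reads_bed(sim$control, paths["control"])
  data.table::fwrite(sim$events, paths["truth"], sep = "\t", na = "NA",
                     quote = FALSE)
  writeLines(paste(names(sim$params),
                   vapply(sim$params, function(p)
                     paste(format(p), collapse = ","), ""),
                   sep = "="), paths["config"])
  paths
}

# 5' end at pos5: plus strand interval [pos5, pos5+len), minus strand
# interval [pos5-len+1, pos5+1).
write_reads_bed <- function(reads, path, read_len = 36L) {
  start <- ifelse(reads$strand == "+", reads$pos5,
                  pmax(0L, reads$pos5 - read_len + 1L))
  end <- ifelse(reads$strand == "+", reads$pos5 + read_len, reads$pos5 + 1L)
  data.table::fwrite(
    data.table::data.table(reads$chrom, start, end, ".", 0L, reads$strand),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a heterotypic factor pair with a fixed spacing
#'
#' Plants \code{n_pairs} anchor (factor B) events with their motif at a
#' random orientation, and a factor-A event with its motif at exactly
#' offset \code{d} in the anchor's motif orientation (a minus-oriented
#' anchor places A at \code{pos_B - d}). Independent background events for
#' both factors are added. Only event locations and the motif-planted
#' genome are produced; reads can be layered on with
#' \code{\link{simulate_dataset}} if needed.
#'
#' @param d Planted signed offset in bp (|d| <= 100).
#' @param n_pairs Number of anchor/partner pairs.
#' @param pwm_B,pwm_A PWMs or consensus strings for the two factors.
#' @param n_background Independent background events per factor.
#' @param genome_length Genome length; default scales with the event
#'   count so anchors sit in clean flanks.
#' @param seed Integer seed.
#' @param chrom Contig name.
#' @return List with \code{genome}, \code{events_A}, \code{events_B}
#'   (anchor table includes motif \code{strand}), \code{d}, \code{params}.
#' @export
simulate_spacing_pair <- function(d, n_pairs, pwm_B = "GGGTGGGGAG",
                                  pwm_A = "TTATGCAAAT",
                                  n_background = 100L,
                                  genome_length = NULL, seed = 1L,
                                  chrom = "chr1") {
  stopifnot(abs(d) <= 100L)
  set.seed(seed)
  probB <- as_prob_matrix(pwm_B)
  probA <- as_prob_matrix(pwm_A)
  n_total <- n_pairs + 2L * n_background
  if (is.null(genome_length)) genome_length <- max(50000L, n_total * 2500L)
  gvec <- strsplit(random_genome(genome_length), "", fixed = TRUE)[[1L]]
  pos_all <- place_events(n_total, genome_length, clearance = 600L,
                          min_sep = 1200L)
  idx <- sample.int(n_total)
  anchors <- sort(pos_all[idx[seq_len(n_pairs)]])
  bgA <- sort(pos_all[idx[n_pairs + seq_len(n_background)]])
  bgB <- sort(pos_all[idx[n_pairs + n_background + seq_len(n_background)]])
  plant <- function(pos, prob, strand) {
    w <- ncol(prob)
    inst <- sample_motif_instance(prob)
    planted <- if (strand == "+") inst else revcomp(inst)
    start <- pos - (w - 1L) %/% 2L
    gvec[(start + 1L):(start + w)] <<- strsplit(planted, "")[[1L]]
  }
  strandB <- sample(c("+", "-"), n_pairs, replace = TRUE)
  posA_pair <- ifelse(strandB == "+", anchors + d, anchors - d)
  for (i in seq_len(n_pairs)) {
    plant(anchors[i], probB, strandB[i])
    plant(posA_pair[i], probA, sample(c("+", "-"), 1L))
  }
  for (p in bgA) plant(p, probA, sample(c("+", "-"), 1L))
  for (p in bgB) plant(p, probB, sample(c("+", "-"), 1L))
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(gvec, collapse = ""), chrom))
  events_B <- data.table::data.table(
    chrom = chrom, pos = c(anchors, bgB),
    strength = 100, is_pair = rep(c(TRUE, FALSE), c(n_pairs, length(bgB))),
    strand = c(strandB, rep(NA_character_, length(bgB))))
  data.table::setorderv(events_B, "pos")
  events_A <- data.table::data.table(
    chrom = chrom, pos = c(posA_pair, bgA),
    strength = 100, is_pair = rep(c(TRUE, FALSE), c(n_pairs, length(bgA))))
  data.table::setorderv(events_A, "pos")
  list(genome = genome, events_A = events_A, events_B = events_B, d = d,
       params = list(n_pairs = n_pairs, n_background = n_background,
                     genome_length = genome_length, seed = seed))
}
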