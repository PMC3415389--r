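#' Run the full six-phase event-calling and motif-discovery pipeline
#'
#' Phase 1 calls binding events with the sparse-prior EM mixture model and
#' no sequence information; Phases 2-3 discover the explanatory motif as a
#' k-mer equivalence class and PWM from the called events; Phase 4 turns
#' the primary class into a per-base positional prior; Phase 5 re-calls
#' events with that prior (biasing calls toward explanatory sequence
#' without ever forcing them); Phase 6 repeats motif discovery from the
#' improved events. The read spatial distribution is re-estimated from the
#' improved events at the end of each round, so a second round
#' (\code{rounds = 2}) adapts the model to ChIP-exo-shaped data even when
#' initialized with a ChIP-Seq distribution.
#'
#' The pipeline is deterministic: EM has no randomness and all orderings
#' are tie-broken deterministically, so identical inputs and configuration
#' give byte-identical outputs.
#'
#' @param expt ChIP reads: a file path (see \code{format}) or a read table.
#' @param genome Genome: FASTA path or \code{DNAStringSet}.
#' @param ctrl Optional control reads (path or table).
#' @param out_prefix Optional output path prefix; when given, event
#'   tables, motifs (MEME + k-mer class report), the learned read
#'   distribution and a run log are written.
#' @param format Alignment format of \code{expt}/\code{ctrl} paths.
#' @param k_min,k_max k-mer range for motif discovery.
#' @param q Reporting q-value threshold (default 0.01).
#' @param alpha_s Sparse prior override; default \code{sqrt(#reads)} per
#'   region.
#' @param mu Positional prior strength in [0,1) (default 0.8; 0 disables
#'   the prior, making Phase 5 identical to Phase 1).
#' @param read_dist Initial read distribution: \code{"chipseq"},
#'   \code{"chipexo"}, a file path, or a \code{read_dist} object.
#' @param rounds Number of prior-assisted re-estimation rounds (default 1;
#'   use 2 for ChIP-exo-style adaptation).
#' @param flank Motif window half-width (default 30).
#' @param dist_bandwidth Smoothing bandwidth for read-distribution
#'   re-estimation; \code{NULL} = 5 bp, or 1 bp when \code{rounds > 1} or
#'   the initial distribution is the ChIP-exo preset (narrow kernels keep
#'   exo bimodality).
#' @param min_reads Minimum reads per region (default 6).
#' @param motif_annot_dist Radius for annotating events with the primary
#'   motif (bp).
#' @return List with \code{events} (final calls), \code{phase1_events},
#'   \code{motifs} (final \code{gem_class} list), \code{phase1_motifs},
#'   \code{dist} (final read distribution), \code{dist_history} (the
#'   initial distribution followed by the re-estimate after each round),
#'   \code{regions}, \code{log}, \code{status} (\code{"ok"} or
#'   \code{"no signal"}).
#' @export
run_gem <- function(expt, genome, ctrl = NULL, out_prefix = NULL,
                    format = c("bed", "sam"), k_min = 5L, k_max = 13L,
                    q = 0.01, alpha_s = NULL, mu = 0.8,
                    read_dist = "chipseq", rounds = 1L, flank = 30L,
                    dist_bandwidth = NULL, min_reads = 6L,
                    motif_annot_dist = 50L) {
  format <- match.arg(format)
  stopifnot(mu >= 0, mu < 1, k_min <= k_max, rounds >= 1L)
  reads <- if (is.character(expt)) parse_reads(expt, format) else
    data.table::as.data.table(expt)
  ctrl_reads <- if (is.null(ctrl)) NULL else if (is.character(ctrl))
    parse_reads(ctrl, format) else data.table::as.data.table(ctrl)
  if (is.character(genome)) genome <- load_genome(genome)
  lens <- genome_lengths(genome)
  genome_size <- sum(lens)
  exo_init <- identical(read_dist, "chipexo")
  dist <- resolve_read_dist(read_dist)
  if (is.null(dist_bandwidth))
    dist_bandwidth <- if (rounds > 1L || exo_init) 1 else 5
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  say("reads=", nrow(reads), " control=",
      if (is.null(ctrl_reads)) 0L else nrow(ctrl_reads),
      " genome=", genome_size, "bp")

  dist_history <- list(dist)
  regions <- segment_regions(reads, lens, min_reads = min_reads)
  say("regions=", length(regions))
  if (length(regions) == 0L) {
    say("no signal: no region survives segmentation")
    return(finish_run(NULL, NULL, list(), list(), dist, regions, log,
                      "no signal", out_prefix, q))
  }

  phase1 <- call_events(reads, lens, dist, regions = regions,
                        alpha_s = alpha_s)
  phase1$events <- test_significance(phase1$events, reads, ctrl_reads,
                                     genome_size)
  sig1 <- phase1$events[phase1$events$q_value <= q, ]
  say("phase1 events=", nrow(phase1$events), " significant=", nrow(sig1))

  motifs <- if (nrow(sig1) >= 2L)
    discover_motifs(sig1, genome, k_range = k_min:k_max, flank = flank)
  else list()
  phase1_motifs <- motifs
  say("phase1 motifs=", length(motifs))

  final <- phase1
  final_sig <- sig1
  for (r in seq_len(rounds)) {
    if (length(motifs) == 0L) {
      say("round ", r, ": no motif; keeping prior-free calls")
      break
    }
    primary <- motifs[[1L]]
    priors <- region_priors(primary, regions, genome, mu = mu,
                            alpha_s = alpha_s)
    say("round ", r, ": prior C_max=", attr(priors, "C_max"),
        " seed=", primary$seed)
    phase5 <- call_events(reads, lens, dist, priors = priors,
                          regions = regions, alpha_s = alpha_s)
    phase5$events <- test_significance(phase5$events, reads, ctrl_reads,
                                       genome_size)
    phase5$events <- annotate_events(phase5$events, primary$pwm, genome,
                                     max_dist = motif_annot_dist)
    final <- phase5
    final_sig <- phase5$events[phase5$events$q_value <= q, ]
    say("round ", r, ": events=", nrow(phase5$events), " significant=",
        nrow(final_sig))
    # re-estimate the read model around motif-anchored positions when the
    # motif is available: the explanatory sequence marks the binding base
    # absolutely, so the learned distribution stays centered even when the
    # previous round's model mis-centered the calls (the ChIP-exo case)
    est_events <- final_sig
    anchored <- which(!is.na(est_events$motif_offset))
    if (length(anchored) >= 5L) {
      est_events <- est_events[anchored, ]
      est_events$pos <- est_events$pos + est_events$motif_offset
      say("round ", r, ": read model anchored on ", length(anchored),
          " motif-annotated events")
    }
    dist <- tryCatch(
      estimate_distribution(est_events, reads, W = dist$W,
                            bandwidth = dist_bandwidth),
      error = function(e) dist)
    dist_history[[r + 1L]] <- dist
    if (nrow(final_sig) >= 2L) {
      motifs <- discover_motifs(final_sig, genome, k_range = k_min:k_max,
                                flank = flank)
      say("round ", r, ": motifs=", length(motifs))
    }
  }
  res <- finish_run(final$events, phase1$events, motifs, phase1_motifs,
                    dist, regions, log, "ok", out_prefix, q)
  res$dist_history <- dist_history
  res
}

resolve_read_dist <- function(read_dist) {
  if (inherits(read_dist, "read_dist")) read_dist
  else if (read_dist %in% c("chipseq", "chipexo"))
    default_distribution(read_dist)
  else read_distribution(read_dist)
}

finish_run <- function(events, phase1_events, motifs, phase1_motifs, dist,
                       regions, log, status, out_prefix, q) {
  empty <- as_event_table(data.table::data.table(
    chrom = character(), pos = integer(), strength = numeric()))
  if (is.null(events)) events <- empty
  if (is.null(phase1_events)) phase1_events <- empty
  events <- as_event_table(events)
  phase1_events <- as_event_table(phase1_events)
  res <- list(events = events, phase1_events = phase1_events,
              motifs = motifs, phase1_motifs = phase1_motifs, dist = dist,
              regions = regions, log = log, status = status)
  if (!is.null(out_prefix)) {
    write_events(events[events$q_value <= q | is.na(events$q_value), ],
                 paste0(out_prefix, "_events.txt"))
    write_events(phase1_events, paste0(out_prefix, "_phase1_events.txt"))
    if (length(motifs) > 0L) {
      write_meme(lapply(motifs, function(m) m$pwm),
                 paste0(out_prefix, "_motifs.meme"))
      write_kmer_classes(motifs, paste0(out_prefix, "_kmer_classes.txt"))
    }
    write_distribution(dist, paste0(out_prefix, "_read_dist.txt"))
    writeLines(log, paste0(out_prefix, "_log.txt"))
  }
  res
}

#' Annotate events with the nearest primary-motif match
#'
#' Fills \code{motif_offset} (signed distance from the event to the match
#' middle) and \code{motif_strand} for events with a PWM match within
#' \code{max_dist} bp; others stay \code{NA}.
#'
#' @param events Event table.
#' @param pwm A \code{gem_pwm} (NULL leaves the table unchanged).
#' @param genome A \code{DNAStringSet}.
#' @param max_dist Annotation radius in bp.
#' @return The event table with annotation columns filled.
#' @export
annotate_events <- function(events, pwm, genome, max_dist = 50L) {
  events <- data.table::as.data.table(events)
  events$motif_offset <- NA_integer_
  events$motif_strand <- NA_character_
  if (is.null(pwm) || nrow(events) == 0L) return(events[])
  lens <- genome_lengths(genome)
  for (ch in unique(events$chrom)) {
    sel <- which(events$chrom == ch)
    lo <- max(0L, min(events$pos[sel]) - max_dist - pwm$width)
    hi <- min(lens[[ch]], max(events$pos[sel]) + max_dist + pwm$width + 1L)
    if (hi <= lo) next
    m <- scan_pwm(pwm, genome_subseq(genome, ch, lo, hi))
    if (nrow(m) == 0L) next
    m$center <- m$center + lo
    data.table::setorderv(m, "center")
    for (i in sel) {
      d <- m$center - events$pos[i]
      j <- which.min(abs(d))
      if (abs(d[j]) <= max_dist) {
        events$motif_offset[i] <- as.integer(d[j])
        events$motif_strand[i] <- m$strand[j]
      }
    }
  }
  events[]
}
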