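## Pairwise transcription-factor spacing-constraint analysis and the
## spatial-resolution / motif-snapping evaluation utilities.

#' Histogram of factor-A binding offsets around factor-B events
#'
#' For each anchor (factor B) event, the sequence strand is oriented by the
#' nearest B-motif match within \code{orient_radius} bp when one exists
#' (unoriented anchors are kept in the plus frame), and every factor-A
#' event within \code{window} bp contributes one count at its
#' strand-adjusted signed offset. Counts in the distal flanks
#' (\code{[-flank2, -flank1]} and \code{[flank1, flank2]}) provide the
#' Poisson null rate for \code{\link{test_spacing}}.
#'
#' @param events_A,events_B Event tables (independent calls for the two
#'   factors).
#' @param pwm_B Optional \code{gem_pwm} of the anchor factor for
#'   orientation.
#' @param genome Optional \code{DNAStringSet} (required with
#'   \code{pwm_B}).
#' @param window Half-width of the offset window (default 100 -> 201
#'   positions).
#' @param orient_radius Motif search radius around anchors (bp).
#' @param flank1,flank2 Flank window bounds (defaults 200 and 400 bp).
#' @return A \code{spacing_profile}: list with \code{offset}
#'   (\code{-window:window}), \code{count}, \code{n_anchor},
#'   \code{flank_count}, \code{flank_positions}, \code{lambda}.
#' @export
spacing_histogram <- function(events_A, events_B, pwm_B = NULL,
                              genome = NULL, window = 100L,
                              orient_radius = 20L, flank1 = 200L,
                              flank2 = 400L) {
  if (nrow(events_B) == 0L) stop("empty anchor (factor B) event set")
  orient <- anchor_orientation(events_B, pwm_B, genome, orient_radius)
  counts <- integer(2L * window + 1L)
  flank_total <- 0L
  for (ch in unique(events_B$chrom)) {
    a <- sort(events_A$pos[events_A$chrom == ch])
    sel <- which(events_B$chrom == ch)
    for (i in sel) {
      b <- events_B$pos[i]
      lo <- findInterval(b - flank2 - 1L, a) + 1L
      hi <- findInterval(b + flank2, a)
      if (hi < lo) next
      d <- a[lo:hi] - b
      if (orient[i] == "-") d <- -d
      inw <- abs(d) <= window
      if (any(inw))
        counts <- counts + tabulate(d[inw] + window + 1L,
                                    nbins = 2L * window + 1L)
      flank_total <- flank_total + sum(abs(d) >= flank1 & abs(d) <= flank2)
    }
  }
  flank_positions <- 2L * (flank2 - flank1 + 1L)
  structure(list(offset = (-window):window, count = counts,
                 n_anchor = nrow(events_B), flank_count = flank_total,
                 flank_positions = flank_positions,
                 lambda = flank_total / flank_positions),
            class = "spacing_profile")
}

# Strand of the nearest anchor-motif match within `radius` bp of each
# anchor event; "+" when no motif / genome is supplied or no match found.
anchor_orientation <- function(events_B, pwm_B, genome, radius) {
  n <- nrow(events_B)
  orient <- rep("+", n)
  if (is.null(pwm_B) || is.null(genome)) return(orient)
  lens <- genome_lengths(genome)
  w <- pwm_B$width
  for (i in seq_len(n)) {
    ch <- events_B$chrom[i]
    p <- events_B$pos[i]
    lo <- max(0L, p - radius - w)
    hi <- min(lens[[ch]], p + radius + w + 1L)
    m <- scan_pwm(pwm_B, genome_subseq(genome, ch, lo, hi))
    if (nrow(m) == 0L) next
    m$center <- m$center + lo
    m$dist <- abs(m$center - p)
    m <- m[m$dist <= radius, ]
    if (nrow(m) == 0L) next
    data.table::setorderv(m, c("dist", "center"))
    orient[i] <- m$strand[1L]
  }
  orient
}

#' @export
print.spacing_profile <- function(x, ...) {
  cat("spacing profile over [", min(x$offset), ",", max(x$offset),
      "] bp;", x$n_anchor, "anchors; flank lambda =",
      signif(x$lambda, 4), "\n")
  if (!is.null(x$p_corrected)) {
    sig <- x$offset[x$significant]
    cat("  significant offsets:",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Test a spacing profile for significant offsets
#'
#' Each offset's count is tested against an upper-tail Poisson null whose
#' rate is the mean count per position in the distal flanks, Bonferroni
#' corrected by the number of window positions times the total number of
#' pairwise tests performed in the study. Offsets with corrected
#' \code{p < threshold} (default 1e-8) are significant.
#'
#' @param profile A \code{spacing_profile}.
#' @param n_tests_total Total number of pairwise factor tests (>= 1).
#' @param threshold Corrected significance threshold.
#' @return The profile with \code{p_raw}, \code{p_corrected} and
#'   \code{significant} (logical per offset) added.
#' @export
test_spacing <- function(profile, n_tests_total = 1L, threshold = 1e-8) {
  stopifnot(inherits(profile, "spacing_profile"), n_tests_total >= 1L)
  lambda <- profile$lambda
  if (lambda == 0 && any(profile$count > 0))
    lambda <- 1 / profile$flank_positions
  p_raw <- stats::ppois(profile$count - 1L, lambda, lower.tail = FALSE)
  n_pos <- length(profile$offset)
  profile$p_raw <- p_raw
  profile$p_corrected <- pmin(1, p_raw * n_pos * n_tests_total)
  profile$significant <- profile$p_corrected < threshold
  profile
}

#' Write a spacing profile report
#'
#' Tab-delimited: offset, count, p_raw, p_corrected, significant.
#' @param profile A tested \code{spacing_profile}.
#' @param path Output path.
#' @export
write_spacing_profile <- function(profile, path) {
  stopifnot(!is.null(profile$p_corrected))
  utils::write.table(
    data.frame(offset = profile$offset, count = profile$count,
               abs_offset = abs(profile$offset),
               p_raw = profile$p_raw, p_corrected = profile$p_corrected,
               significant = profile$significant),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize spacing constraints for many factor pairs
#'
#' @param profiles Named list of tested \code{spacing_profile}s
#'   ("A_vs_B" entries).
#' @return data.frame with the most significant offset, its absolute
#'   value and count, and the number of significant offsets per pair.
#' @export
spacing_summary <- function(profiles) {
  do.call(rbind, lapply(names(profiles), function(nm) {
    pr <- profiles[[nm]]
    i <- which.min(pr$p_corrected)
    data.frame(pair = nm, best_offset = pr$offset[i],
               best_abs_offset = abs(pr$offset[i]),
               best_count = pr$count[i],
               best_p_corrected = pr$p_corrected[i],
               n_significant = sum(pr$significant))
  }))
}

#' Spatial resolution of event calls against motif positions
#'
#' Pairs every event with the nearest motif middle within \code{max_dist}
#' bp (events without one are excluded), centers the signed offsets by
#' subtracting their mean, and returns the mean absolute centered offset
#' together with the raw offset histogram.
#'
#' @param events Event table.
#' @param motif_centers data.frame with \code{chrom}, \code{center}
#'   (0-based motif middles), e.g. derived from \code{\link{scan_pwm}}.
#' @param max_dist Pairing radius in bp (default 100).
#' @return List with \code{resolution} (mean |centered offset|),
#'   \code{offsets} (raw signed offsets), \code{histogram} (table),
#'   \code{n}.
#' @export
spatial_resolution <- function(events, motif_centers, max_dist = 100L) {
  offsets <- numeric(0)
  for (ch in unique(events$chrom)) {
    mc <- sort(motif_centers$center[motif_centers$chrom == ch])
    if (length(mc) == 0L) next
    for (p in events$pos[events$chrom == ch]) {
      i <- findInterval(p, mc)
      cand <- mc[pmax(1L, i):pmin(length(mc), i + 1L)]
      d <- p - cand[which.min(abs(p - cand))]
      if (abs(d) <= max_dist) offsets <- c(offsets, d)
    }
  }
  if (length(offsets) == 0L)
    stop("no event within ", max_dist, " bp of a motif")
  centered <- offsets - mean(offsets)
  list(resolution = mean(abs(centered)), offsets = offsets,
       histogram = table(offsets), n = length(offsets))
}

#' Snap events to the nearest motif match
#'
#' Relocates each event to the middle of the nearest PWM match within
#' \code{max_dist} bp (inclusive); events with no match in range are left
#' unchanged. This is the comparison baseline for motif-aware spacing
#' analyses, not part of the calling pipeline itself.
#'
#' @param events Event table.
#' @param pwm A \code{gem_pwm}.
#' @param genome A \code{DNAStringSet}.
#' @param max_dist Snap radius in bp (default 50).
#' @return The event table with \code{pos} updated.
#' @export
snap_to_motif <- function(events, pwm, genome, max_dist = 50L) {
  events <- data.table::as.data.table(events)
  lens <- genome_lengths(genome)
  for (ch in unique(events$chrom)) {
    sel <- which(events$chrom == ch)
    lo <- max(0L, min(events$pos[sel]) - max_dist - pwm$width)
    hi <- min(lens[[ch]], max(events$pos[sel]) + max_dist + pwm$width + 1L)
    m <- scan_pwm(pwm, genome_subseq(genome, ch, lo, hi))
    if (nrow(m) == 0L) next
    centers <- sort(unique(m$center + lo))
    for (i in sel) {
      p <- events$pos[i]
      j <- findInterval(p, centers)
      cand <- centers[pmax(1L, j):pmin(length(centers), j + 1L)]
      d <- abs(cand - p)
      if (min(d) <= max_dist) {
        best <- cand[d == min(d)]
        events$pos[i] <- min(best)    # tie toward the lower coordinate
      }
    }
  }
  data.table::setorderv(events, c("chrom", "pos"))
  events[]
}
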