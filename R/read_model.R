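#' Default read spatial distributions
#'
#' Built-in starting distributions for the two supported assay types, used
#' to initialize event calling before any data-driven re-estimation.
#' Both are expressed in the plus-strand frame (minus strand is the mirror
#' image) over the symmetric support \code{[-W, W]}.
#'
#' \describe{
#'   \item{\code{chipseq}}{Unimodal, peaked 37 bp upstream of the event
#'     (sonication-size fragments place plus-strand 5' ends upstream) with a
#'     20 bp double-exponential decay length, so the tails are essentially
#'     confined to +/- 300 bp.}
#'   \item{\code{chipexo}}{Tight bimodal shape produced by exonuclease
#'     trimming: a dominant peak 10 bp upstream and a minor one 14 bp
#'     downstream, with almost all mass within +/- 50 bp.}
#' }
#'
#' @param mode \code{"chipseq"} or \code{"chipexo"}.
#' @param W Support half-width in bp.
#' @return A \code{\link{read_dist}}.
#' @export
default_distribution <- function(mode = c("chipseq", "chipexo"), W = 500L) {
  mode <- match.arg(mode)
  d <- (-W):W
  p <- if (mode == "chipseq") {
    # sharp core (12 bp decay) over a broad fragment-length tail (80 bp)
    0.8 * exp(-abs(d + 37) / 12) / 24 + 0.2 * exp(-abs(d + 37) / 80) / 160
  } else {
    0.7 * exp(-abs(d + 10) / 3) + 0.3 * exp(-abs(d - 14) / 3)
  }
  read_dist(d, p, W = W)
}

#' Estimate the read spatial distribution from called events
#'
#' Re-estimates the empirical distribution of read 5' offsets around
#' binding events, the step that lets the model adapt to the assay at hand
#' (e.g. learn the sharp ChIP-exo shape starting from a ChIP-Seq prior).
#' The strongest \code{top_k} events are used; each read within the support
#' of its nearest event contributes its signed offset (read pos5 - event
#' pos) once, with minus-strand reads mirrored into the plus-strand frame. The offset histogram is
#' Gaussian-kernel smoothed, floored and renormalized.
#'
#' @param events Event table with \code{chrom}, \code{pos}, \code{strength}.
#' @param reads Read table from \code{\link{parse_reads}}.
#' @param W Support half-width (bp).
#' @param top_k Number of strongest events used for estimation.
#' @param bandwidth Gaussian smoothing bandwidth in bp; use a narrow kernel
#'   (1 bp) when refining ChIP-exo rounds so bimodality is preserved.
#' @return A \code{\link{read_dist}}.
#' @export
estimate_distribution <- function(events, reads, W = 500L, top_k = 1000L,
                                  bandwidth = 5) {
  stopifnot(nrow(events) >= 1L)
  events <- events[order(-events$strength), , drop = FALSE]
  events <- utils::head(events, top_k)
  counts <- numeric(2L * W + 1L)
  n_used <- 0L
  for (ch in unique(events$chrom)) {
    r <- reads[reads$chrom == ch, ]
    ev <- sort(events$pos[events$chrom == ch])
    if (nrow(r) == 0L || length(ev) == 0L) next
    # each read contributes once, to its nearest event
    i <- findInterval(r$pos5, ev)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(ev))
    nearest <- ifelse(abs(r$pos5 - ev[lo]) <= abs(r$pos5 - ev[hi]),
                      ev[lo], ev[hi])
    d <- r$pos5 - nearest
    d <- ifelse(r$strand == "+", d, -d)
    inside <- abs(d) <= W
    counts <- counts + tabulate(d[inside] + W + 1L, nbins = 2L * W + 1L)
    n_used <- n_used + sum(inside)
  }
  if (n_used == 0L)
    stop("no reads within ", W, " bp of any event; cannot estimate ",
         "read distribution")
  if (bandwidth > 0) counts <- smooth_gaussian(counts, bandwidth)
  read_dist((-W):W, counts, W = W)
}

# Discrete Gaussian kernel smoothing with renormalizing edge correction.
smooth_gaussian <- function(x, bandwidth) {
  half <- max(1L, ceiling(4 * bandwidth))
  k <- stats::dnorm((-half):half, sd = bandwidth)
  k <- k / sum(k)
  n <- length(x)
  padded <- c(numeric(half), x, numeric(half))
  sm <- stats::filter(padded, k, sides = 2L)[(half + 1L):(half + n)]
  # mass lost off the edges is restored by rescaling
  as.numeric(sm) * sum(x) / sum(sm)
}

# Total-variation distance between two read distributions on a common
# support (used throughout the tests against simulator truth).
dist_tv <- function(a, b) {
  W <- max(a$W, b$W)
  pa <- pb <- numeric(2L * W + 1L)
  pa[a$offset + W + 1L] <- a$prob
  pb[b$offset + W + 1L] <- b$prob
  sum(abs(pa - pb)) / 2
}
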