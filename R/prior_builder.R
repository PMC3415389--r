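## Phase 4: convert the primary k-mer equivalence class into a per-base
## positional prior over each region.

#' Positional prior counts from a k-mer equivalence class
#'
#' Occurrences of every member k-mer (both strands) in the region sequence
#' are located simultaneously with a constant-width multi-pattern matcher
#' (\code{\link[Biostrings]{matchPDict}}); each occurrence marks the
#' expected binding event base — the occurrence start plus the member's
#' expected event offset, mirror-adjusted on the minus strand — and adds
#' that member's positive-set hit count there. Contributions from several
#' members landing on the same base are summed. Bases implied outside the
#' region are clipped.
#'
#' @param kmer_class A \code{gem_class} (members need \code{kmer},
#'   \code{offset}, \code{pos_hits}).
#' @param region_seq Region sequence (character, A/C/G/T/N).
#' @param pdicts Optional preprocessed dictionaries from one
#'   \code{class_pdicts()} call, reused across regions.
#' @return Integer vector of prior counts \code{C}, one per region base.
#' @export
build_prior_counts <- function(kmer_class, region_seq, pdicts = NULL) {
  members <- kmer_class$members
  stopifnot(nrow(members) > 0L)
  M <- nchar(region_seq)
  C <- integer(M)
  k <- nchar(members$kmer[1L])
  if (is.null(pdicts)) pdicts <- class_pdicts(members)
  subject <- Biostrings::DNAString(region_seq)
  offs <- as.integer(round(members$offset))
  hits <- members$pos_hits
  fwd_starts <- start_list(pdicts$fwd, subject)
  rev_starts <- start_list(pdicts$rev, subject)
  for (i in seq_len(nrow(members))) {
    for (s in fwd_starts[[i]]) {            # 1-based occurrence start
      b <- (s - 1L) + offs[i]               # implied event base, 0-based
      if (b >= 0L && b < M) C[b + 1L] <- C[b + 1L] + hits[i]
    }
    if (pdicts$palindrome[i]) next          # palindrome: one orientation
    for (s in rev_starts[[i]]) {
      b <- (s - 1L) + (k - 1L) - offs[i]    # mirror-adjusted
      if (b >= 0L && b < M) C[b + 1L] <- C[b + 1L] + hits[i]
    }
  }
  C
}

# Preprocessed constant-width dictionaries for the class members and their
# reverse complements (built once, matched against many regions).
class_pdicts <- function(members) {
  list(fwd = Biostrings::PDict(members$kmer),
       rev = Biostrings::PDict(revcomp(members$kmer)),
       palindrome = members$kmer == revcomp(members$kmer))
}

# Occurrence starts of a preprocessed dictionary in a subject, as a list
# parallel to the patterns.
start_list <- function(pdict, subject) {
  m <- Biostrings::matchPDict(pdict, subject)
  lapply(seq_along(m), function(i) IRanges::start(m[[i]]))
}

#' Convert prior counts into per-base alpha values
#'
#' \code{alpha_m = mu * alpha_s * C_m / C_max}, where \code{C_max} is the
#' global maximum prior count across all evaluated regions, so every
#' \code{alpha_m} stays strictly below \code{alpha_s} (the prior can bias,
#' but never force, an event call). \code{mu = 0} disables the prior.
#'
#' @param C Integer prior counts for one region.
#' @param alpha_s Sparse prior scalar for the region.
#' @param mu Prior strength in \code{[0, 1)} (default 0.8).
#' @param C_max Global maximum count (default \code{max(C)}).
#' @return Numeric vector of \code{alpha_m} values.
#' @export
alpha_from_counts <- function(C, alpha_s, mu = 0.8, C_max = NULL) {
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1)")
  stopifnot(alpha_s > 0)
  if (is.null(C_max)) C_max <- max(C)
  if (C_max <= 0) return(numeric(length(C)))
  mu * alpha_s * C / C_max
}

#' Per-region positional priors for event calling
#'
#' Computes prior counts for every region, takes the global count maximum,
#' and converts counts to per-base \code{alpha_m} using each region's own
#' sparse prior scalar (\code{sqrt(#reads)} unless overridden).
#'
#' @param kmer_class A \code{gem_class}.
#' @param regions Regions from \code{\link{segment_regions}}.
#' @param genome A \code{DNAStringSet}.
#' @param mu Prior strength (default 0.8).
#' @param alpha_s Optional fixed sparse prior scalar.
#' @return List of per-base alpha vectors parallel to \code{regions}, with
#'   attribute \code{C_max}.
#' @export
region_priors <- function(kmer_class, regions, genome, mu = 0.8,
                          alpha_s = NULL) {
  pdicts <- class_pdicts(kmer_class$members)
  counts <- lapply(regions, function(r)
    build_prior_counts(kmer_class,
                       genome_subseq(genome, r$chrom, r$start, r$end),
                       pdicts = pdicts))
  C_max <- max(c(0L, unlist(counts, use.names = FALSE)))
  alphas <- lapply(seq_along(regions), function(i) {
    a_s <- if (is.null(alpha_s)) sqrt(nrow(regions[[i]]$reads)) else alpha_s
    if (C_max == 0L) numeric(length(counts[[i]]))
    else alpha_from_counts(counts[[i]], a_s, mu, C_max)
  })
  attr(alphas, "C_max") <- C_max
  attr(alphas, "counts") <- counts
  alphas
}
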