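#' Parse aligned reads from BED or SAM
#'
#' Reduces each alignment to the three fields the event model uses: the
#' chromosome, the 0-based genomic coordinate of the read's 5' end, and the
#' strand. For a minus-strand alignment the 5' end is the highest coordinate
#' of the alignment interval. BED intervals are interpreted as half-open and
#' 0-based; SAM coordinates (1-based) are converted at this boundary and
#' nowhere else.
#'
#' @param path Path to an alignment file.
#' @param format Either \code{"bed"} (BED6 or more columns) or \code{"sam"}
#'   (headerless SAM is tolerated; unmapped records are skipped with a
#'   logged count).
#' @param mapq_min Optional minimum MAPQ for SAM records; \code{NULL}
#'   (default) keeps everything, since alignment filtering policy is treated
#'   as upstream of this tool.
#' @param dup_cap Optional per-base-per-strand duplicate cap; \code{NULL}
#'   (default) keeps all reads so that deep homotypic sites are not
#'   truncated.
#' @return A \code{data.table} with columns \code{chrom} (character),
#'   \code{pos5} (integer, 0-based) and \code{strand} (\code{"+"}/\code{"-"}),
#'   sorted by chromosome then position.
#' @export
parse_reads <- function(path, format = c("bed", "sam"), mapq_min = NULL,
                        dup_cap = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  reads <- if (format == "bed") parse_bed(path) else parse_sam(path, mapq_min)
  if (nrow(reads) > 0L && any(reads$pos5 < 0L))
    stop("negative 5' coordinate after conversion in ", path)
  if (!is.null(dup_cap)) {
    stopifnot(dup_cap >= 1)
    reads <- reads[, utils::head(.SD, dup_cap), by = c("chrom", "pos5", "strand")]
  }
  data.table::setorderv(reads, c("chrom", "pos5"))
  data.table::setcolorder(reads, c("chrom", "pos5", "strand"))
  reads[]
}

parse_bed <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = 1L)),
    error = function(e) stop("cannot read BED file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L)
    return(data.table::data.table(chrom = character(), pos5 = integer(),
                                  strand = character()))
  if (ncol(dt) < 6L)
    stop("BED file ", path, " has fewer than 6 columns; strand is required")
  start <- suppressWarnings(as.integer(dt[[2L]]))
  end <- suppressWarnings(as.integer(dt[[3L]]))
  strand <- as.character(dt[[6L]])
  bad <- which(is.na(start) | is.na(end) | end <= start |
                 !(strand %in% c("+", "-")))
  if (length(bad) > 0L)
    stop("malformed BED line ", bad[1L], " in ", path)
  data.table::data.table(
    chrom = as.character(dt[[1L]]),
    pos5 = ifelse(strand == "+", start, end - 1L),
    strand = strand)
}

# Reference-consumed length of an alignment from its CIGAR: M, D, N, =, X
# advance the reference; I, S, H, P do not.
cigar_ref_length <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    m <- regmatches(cigar[i], ops[i])[[1L]]
    if (length(m) == 0L) return(NA_integer_)
    n <- as.integer(sub("[MIDNSHP=X]$", "", m))
    op <- sub("^\\d+", "", m)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L))
}

parse_sam <- function(path, mapq_min = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  if (length(body) == 0L)
    return(data.table::data.table(chrom = character(), pos5 = integer(),
                                  strand = character()))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM line ", body[which(nf < 11L)[1L]], " in ", path)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  if (anyNA(flag) || anyNA(pos1))
    stop("malformed SAM line ",
         body[which(is.na(flag) | is.na(pos1))[1L]], " in ", path)
  unmapped <- bitwAnd(flag, 4L) != 0L
  if (any(unmapped))
    message("parse_reads: skipped ", sum(unmapped), " unmapped SAM record(s)")
  keep <- !unmapped
  if (!is.null(mapq_min)) {
    mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
    keep <- keep & !is.na(mapq) & mapq >= mapq_min
  }
  if (!any(keep))
    return(data.table::data.table(chrom = character(), pos5 = integer(),
                                  strand = character()))
  fields <- fields[keep]
  flag <- flag[keep]
  pos1 <- pos1[keep]
  chrom <- vapply(fields, `[[`, "", 3L)
  reflen <- cigar_ref_length(vapply(fields, `[[`, "", 6L))
  if (anyNA(reflen))
    stop("malformed CIGAR in SAM record (line ",
         body[keep][which(is.na(reflen))[1L]], ") in ", path)
  minus <- bitwAnd(flag, 16L) != 0L
  # 0-based 5' end: plus strand = POS-1; minus strand = rightmost base.
  pos5 <- ifelse(minus, pos1 - 1L + reflen - 1L, pos1 - 1L)
  data.table::data.table(chrom = chrom, pos5 = as.integer(pos5),
                         strand = ifelse(minus, "-", "+"))
}

#' Write and read called binding events
#'
#' Tab-delimited with a header line; columns are \code{chrom}, \code{pos}
#' (0-based single-base event coordinate), \code{strength} (effective read
#' count), \code{fold} (ChIP/control enrichment, \code{Inf} without
#' control), \code{p_value}, \code{q_value}, \code{motif_offset} and
#' \code{motif_strand} (\code{NA} when no motif annotation exists).
#'
#' @param events A data.frame of events sorted by (chrom, pos).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_event_table(events)
  if (nrow(events) > 0L) {
    o <- order(events$chrom, events$pos)
    if (!identical(o, seq_len(nrow(events))))
      stop("events must be sorted by (chrom, pos) before writing")
  }
  data.table::fwrite(events, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = "chrom"))
  as_event_table(dt)
}

event_columns <- c("chrom", "pos", "strength", "fold", "p_value", "q_value",
                   "motif_offset", "motif_strand")

# Coerce to the canonical event table layout, filling absent annotation
# columns with NA and checking the field invariants.
as_event_table <- function(events) {
  events <- data.table::as.data.table(events)
  for (col in event_columns)
    if (!col %in% names(events))
      events[[col]] <- rep(if (col == "motif_strand") NA_character_
                           else NA_real_, nrow(events))
  events <- events[, event_columns, with = FALSE]
  events$chrom <- as.character(events$chrom)
  events$pos <- as.integer(events$pos)
  events$motif_offset <- as.integer(events$motif_offset)
  events$motif_strand <- as.character(events$motif_strand)
  if (nrow(events) > 0L) {
    stopifnot(all(events$strength >= 0),
              all(is.na(events$p_value) |
                    (events$p_value > 0 & events$p_value <= 1)))
    ok <- is.na(events$q_value) | is.na(events$p_value) |
      events$q_value >= events$p_value - 1e-12
    stopifnot(all(ok))
  }
  events[]
}

#' Read spatial distribution: construction and file I/O
#'
#' A read spatial distribution gives the probability of observing a read 5'
#' end at a signed base offset from a binding event, in the plus-strand
#' frame; the minus-strand distribution is its mirror image
#' (\code{p_minus(d) = p_plus(-d)}). The support is the symmetric interval
#' \code{[-W, W]}; probabilities are floored at \code{1e-9} and normalized
#' to sum to one.
#'
#' @param offset Integer offsets (need not cover the full support).
#' @param prob Non-negative weights for \code{offset}.
#' @param W Half-width of the support; defaults to \code{max(abs(offset))}.
#' @return An object of class \code{read_dist} with fields \code{W},
#'   \code{offset} (\code{-W:W}) and \code{prob}.
#' @export
read_dist <- function(offset, prob, W = NULL) {
  offset <- as.integer(offset)
  stopifnot(length(offset) == length(prob), length(offset) > 0L,
            !is.unsorted(offset, strictly = TRUE))
  if (any(prob < 0)) stop("negative probability in read distribution")
  if (is.null(W)) W <- max(abs(offset))
  W <- as.integer(W)
  stopifnot(W >= max(abs(offset)))
  p <- numeric(2L * W + 1L)
  p[offset + W + 1L] <- prob
  p <- pmax(p, 1e-9)
  p <- p / sum(p)
  structure(list(W = W, offset = (-W):W, prob = p), class = "read_dist")
}

#' @rdname read_dist
#' @param path Two-column whitespace-delimited text: signed offset (bp) and
#'   probability, offsets strictly increasing.
#' @export
read_distribution <- function(path) {
  dt <- utils::read.table(path, header = FALSE, col.names = c("offset", "prob"))
  if (is.unsorted(dt$offset, strictly = TRUE))
    stop("read distribution offsets must be strictly increasing in ", path)
  if (any(dt$prob < 0))
    stop("negative probability in read distribution file ", path)
  read_dist(dt$offset, dt$prob)
}

#' @rdname read_dist
#' @param dist A \code{read_dist} object.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "read_dist"))
  utils::write.table(data.frame(offset = dist$offset, prob = dist$prob),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.read_dist <- function(x, ...) {
  cat("read spatial distribution on [", -x$W, ",", x$W, "] bp; mode at",
      x$offset[which.max(x$prob)], "bp\n")
  invisible(x)
}

# Probability of a read 5' end at signed offset d from an event, given the
# read strand; offsets outside the support have probability zero.
dist_prob <- function(dist, d, strand = "+") {
  d <- ifelse(strand == "+", d, -d)
  p <- numeric(length(d))
  inside <- abs(d) <= dist$W
  p[inside] <- dist$prob[d[inside] + dist$W + 1L]
  p
}

#' Load a genome from FASTA and query subsequences
#'
#' \code{load_genome} reads a FASTA file into a named
#' \code{\link[Biostrings]{DNAStringSet}} (names truncated at the first
#' whitespace, as aligners do). \code{genome_subseq} extracts a 0-based
#' half-open window as an uppercase character string; out-of-range queries
#' are an error, never a silent wraparound.
#'
#' @param path FASTA file path.
#' @return A \code{DNAStringSet}.
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname load_genome
#' @param genome A \code{DNAStringSet}.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || end <= start)
    stop("subsequence [", start, ",", end, ") out of range for ", chrom,
         " (length ", len, ")")
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end)))
}

genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms A list of \code{gem_pwm} objects (see
#'   \code{\link{build_weighted_pwm}}).
#' @param path Output path.
#' @param background Optional length-4 background frequency vector
#'   (A, C, G, T); defaults to the first PWM's background.
#' @export
write_meme <- function(pwms, path, background = NULL) {
  if (inherits(pwms, "gem_pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  bg <- background
  if (is.null(bg) && length(pwms) > 0L) bg <- pwms[[1L]]$background
  if (is.null(bg)) bg <- rep(0.25, 4L)
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  writeLines(sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
             con)
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    nm <- if (!is.null(p$name)) p$name else pwm_consensus(p)
    writeLines(c("", paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %.3g",
                         p$width, max(1L, round(p$nsites %||% 1)),
                         p$p_hyper %||% 1)), con)
    for (j in seq_len(p$width))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         p$prob[1, j], p$prob[2, j], p$prob[3, j], p$prob[4, j]),
                 con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
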