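#' Segment the genome into independent separable regions
#'
#' Reads are grouped per chromosome; a new region starts at any gap between
#' consecutive read 5' positions larger than \code{gap} bp, and regions
#' holding fewer than \code{min_reads} reads are dropped. Region bounds are
#' the first/last read extended by \code{W} and clipped to the chromosome,
#' so every candidate event position that could explain a region read lies
#' inside the region.
#'
#' @param reads Read table (\code{chrom}, \code{pos5}, \code{strand}).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param min_reads Minimum reads per region (default 6).
#' @param gap Gap threshold in bp (default 500).
#' @param W Bound extension, matching the read-distribution support.
#' @return A list of regions, each a list with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{reads}.
#' @export
segment_regions <- function(reads, chrom_lengths, min_reads = 6L,
                            gap = 500L, W = 500L) {
  regions <- list()
  for (ch in intersect(unique(reads$chrom), names(chrom_lengths))) {
    r <- reads[reads$chrom == ch, ]
    r <- r[order(r$pos5), ]
    if (nrow(r) == 0L) next
    grp <- cumsum(c(0L, diff(r$pos5) > gap))
    for (g in split(seq_len(nrow(r)), grp)) {
      if (length(g) < min_reads) next
      first <- r$pos5[g[1L]]
      last <- r$pos5[g[length(g)]]
      regions[[length(regions) + 1L]] <- list(
        chrom = ch,
        start = max(0L, first - W),
        end = min(as.integer(chrom_lengths[[ch]]), last + W + 1L),
        reads = r[g, ])
    }
  }
  regions
}

#' Sparse-prior M-step with component elimination
#'
#' Closed-form maximizer of the expected complete-data penalized
#' log-likelihood under the negative Dirichlet prior: the effective read
#' count of each component is decreased by the sparseness pseudo-count
#' \code{alpha_s} and increased by its positional pseudo-count
#' \code{alpha[m]}; components whose adjusted count is driven to zero are
#' eliminated and the model restructured without them.
#'
#' @param N_eff Per-component effective read counts (non-negative).
#' @param alpha_s Sparse prior scalar, \code{> 0} (0 recovers plain ML).
#' @param alpha Per-component positional prior, \code{0 <= alpha < alpha_s}
#'   elementwise (when \code{alpha_s > 0}).
#' @return List with \code{pi} (mixing probabilities over survivors, summing
#'   to 1) and \code{active} (logical survivor mask over the input
#'   components). All-zero input yields an empty survivor set.
#' @export
m_step_update <- function(N_eff, alpha_s, alpha = numeric(length(N_eff))) {
  stopifnot(length(alpha) == length(N_eff), all(N_eff >= -1e-9),
            alpha_s >= 0, all(alpha >= 0))
  if (alpha_s > 0 && any(alpha >= alpha_s))
    stop("positional prior alpha must be strictly below alpha_s")
  u <- pmax(0, N_eff - alpha_s + alpha)
  active <- u > 0
  if (!any(active)) return(list(pi = numeric(0), active = active))
  list(pi = u[active] / sum(u[active]), active = active)
}

# Read-likelihood matrix for a region: L[n, j] = p(read n | event at
# position start + j - 1), looked up from the strand-appropriate mirror of
# the read distribution. Rows are shifted slices of the distribution.
region_likelihood <- function(region, dist) {
  M <- region$end - region$start
  W <- dist$W
  ext <- c(numeric(M), dist$prob, numeric(M))  # guard against overflow
  pos <- region$reads$pos5 - region$start      # 0-based within region
  plus <- region$reads$strand == "+"
  # plus-strand row n is a reversed slice of the distribution starting at
  # pos_n (d_j = pos_n - (j-1)); minus-strand rows are the mirror slice
  base <- ifelse(plus, pos + W + 1L + M, W + 1L + M - pos)
  sign <- ifelse(plus, -1L, 1L)
  idx <- base + outer(sign, 0:(M - 1L), "*")
  matrix(ext[idx], nrow = length(pos))
}

#' Fit the binding-event mixture model to one region by EM
#'
#' Every base of the region is a candidate event. The E step assigns each
#' read fractionally to candidate events in proportion to \code{pi_m} times
#' the read-distribution probability of its signed offset; the M step is
#' \code{\link{m_step_update}}. The sparse prior \code{alpha_s} is annealed
#' linearly from zero over the first \code{anneal_iters} iterations (the
#' positional prior is scaled down in step so it always stays strictly below
#' the sparse prior), which avoids premature component death while the read
#' assignments are still diffuse.
#'
#' The penalized objective (data log-likelihood plus the negative-Dirichlet
#' term) is tracked per model: eliminating a component removes its prior
#' term, so the objective is only comparable between iterations that share
#' a surviving set. Within any fixed surviving set the update never
#' decreases the objective (the M step is the exact maximizer there); the
#' per-iteration trace records the objective, the previous parameters
#' re-evaluated under the current iteration's prior
#' (\code{objective_prev_restricted}), and whether the iteration
#' restructured the model. Convergence is the relative objective change
#' falling below \code{tol} on a stable model.
#'
#' @param region A region from \code{\link{segment_regions}}.
#' @param dist A \code{\link{read_dist}}.
#' @param prior Optional per-base positional prior \code{alpha_m} over the
#'   region (length \code{end - start}); \code{NULL} means prior-free.
#' @param alpha_s Sparse prior scalar; default \code{sqrt(#reads)}.
#' @param tol Relative objective-change convergence threshold.
#' @param max_iter Iteration cap.
#' @param anneal_iters Annealing length in iterations.
#' @param merge_bp Surviving components closer than this many bp are merged
#'   into one event (position of the strongest, ties toward the lower
#'   coordinate) — exact symmetric read piles can otherwise leave a
#'   2-component plateau.
#' @param refine_bp After convergence each surviving component moves to
#'   the position within this radius that maximizes its effective read
#'   mass plus positional prior (elimination is irreversible, so a
#'   survivor can otherwise sit a few bases off the optimum); EM is
#'   re-run after each sweep. 0 disables refinement.
#' @param refine_sweeps Maximum move-and-re-fit rounds.
#' @param refine_prior_weight Log-likelihood units per positional-prior
#'   pseudo-count when scoring candidate positions during refinement: the
#'   exchange rate at which read evidence overrides the sequence prior.
#' @return List with \code{events} (data.table \code{chrom}, \code{pos},
#'   \code{strength}), \code{state} (positions, pi, alpha_s, alpha, active
#'   mask, responsibilities \code{gamma}, per-iteration \code{trace}),
#'   \code{converged}, \code{n_iter}.
#' @export
em_fit <- function(region, dist, prior = NULL, alpha_s = NULL, tol = 1e-5,
                   max_iter = 500L, anneal_iters = 50L, merge_bp = 3L,
                   refine_bp = 20L, refine_sweeps = 4L,
                   refine_prior_weight = 1) {
  N <- nrow(region$reads)
  M <- region$end - region$start
  stopifnot(N > 0L, M > 0L)
  if (is.null(alpha_s)) alpha_s <- sqrt(N)
  if (is.null(prior)) prior <- numeric(M)
  stopifnot(length(prior) == M)
  if (alpha_s > 0 && any(prior >= alpha_s))
    stop("positional prior must be strictly below alpha_s")
  L <- region_likelihood(region, dist)
  idx0 <- which(colSums(L) > 0)     # positions no read can ever support
  st <- list(idx = idx0, pi = rep(1 / length(idx0), length(idx0)),
             trace = list(), iter = 0L, converged = FALSE)
  st <- em_loop(L, prior, st, alpha_s, anneal_iters, tol, max_iter)
  # positional refinement: greedy elimination can strand a surviving
  # component a few bases off the penalized-likelihood optimum, because a
  # candidate position, once eliminated, can never regain mass. Each
  # survivor's mass is re-spread over its +/- refine_bp neighborhood and
  # the annealed competition re-run, so the final position balances read
  # likelihood against the positional prior exactly as the M step defines.
  if (length(st$idx) > 0L && refine_bp > 0L) {
    for (sweep in seq_len(refine_sweeps)) {
      moved <- refine_positions(L, prior, st, refine_bp,
                                 prior_weight = refine_prior_weight)
      if (!moved$moved) break
      st <- moved$st
      st <- em_loop(L, prior, st, alpha_s, anneal_iters = 0L, tol,
                    max_iter = 200L)
      if (length(st$idx) == 0L) break
    }
  }
  trace <- if (length(st$trace))
    as.data.frame(do.call(rbind, st$trace)) else NULL
  if (length(st$idx) == 0L)
    return(list(events = empty_region_events(region), state = NULL,
                converged = TRUE, n_iter = st$iter))
  # final responsibilities and strengths on the converged model
  La <- L[, st$idx, drop = FALSE]
  num <- sweep(La, 2L, st$pi, "*")
  mix <- rowSums(num)
  nz <- mix > 0
  gamma <- num[nz, , drop = FALSE] / mix[nz]
  N_eff <- colSums(gamma)
  positions <- region$start + st$idx - 1L
  ev <- merge_close_components(positions, N_eff, merge_bp)
  events <- data.table::data.table(chrom = region$chrom, pos = ev$pos,
                                   strength = ev$strength)
  state <- list(positions = positions, pi = st$pi, gamma = gamma,
                N_eff = N_eff, alpha_s = alpha_s,
                alpha = prior[st$idx], active = seq_len(M) %in% st$idx,
                trace = trace)
  list(events = events, state = state, converged = st$converged,
       n_iter = st$iter)
}

# Annealed EM with component elimination over the candidate columns in
# st$idx; appends per-iteration objective rows to st$trace. anneal_iters =
# 0 applies the full sparse prior from the first iteration.
em_loop <- function(L, prior, st, alpha_s, anneal_iters, tol, max_iter) {
  La <- L[, st$idx, drop = FALSE]
  alpha_act <- prior[st$idx]
  pi <- st$pi
  idx <- st$idx
  J_prev <- NA_real_
  it <- 0L
  st$converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    st$iter <- st$iter + 1L
    ramp <- if (anneal_iters > 0L) min(1, (it - 1) / anneal_iters) else 1
    a_s <- alpha_s * ramp
    a_m <- alpha_act * ramp
    # E step in closed form: N_eff_m = pi_m * sum_n L_nm / mix_n without
    # materializing the responsibility matrix
    mix <- as.numeric(La %*% pi)
    wr <- ifelse(mix > 0, 1 / mix, 0)
    N_eff <- pi * as.numeric(crossprod(La, wr))
    up <- m_step_update(N_eff, a_s, a_m)
    if (length(up$pi) == 0L) {
      st$idx <- integer(0); st$pi <- numeric(0); st$converged <- TRUE
      return(st)
    }
    surv <- up$active
    pi_new <- up$pi
    # objective of the updated model, and of the previous parameters
    # restricted to the same (restructured) model
    J <- region_objective(La[, surv, drop = FALSE], pi_new, a_s, a_m[surv])
    J_restr <- region_objective(La[, surv, drop = FALSE],
                                pi[surv] / sum(pi[surv]), a_s, a_m[surv])
    if (!is.finite(J))
      stop("non-finite penalized objective at EM iteration ", st$iter)
    same_model <- all(surv)
    st$trace[[length(st$trace) + 1L]] <-
      c(iter = st$iter, objective = J,
        objective_prev_restricted = J_restr,
        n_active = length(pi_new), annealed = as.numeric(ramp < 1),
        restructured = as.numeric(!same_model))
    idx <- idx[surv]
    La <- La[, surv, drop = FALSE]
    alpha_act <- alpha_act[surv]
    pi <- pi_new
    if (same_model && it > anneal_iters && !is.na(J_prev) &&
        abs(J - J_prev) <= tol * (abs(J_prev) + 1e-12)) {
      st$converged <- TRUE
      break
    }
    J_prev <- if (same_model) J else NA_real_
  }
  st$idx <- idx
  st$pi <- pi
  st
}

# One refinement sweep over surviving components (strongest first): each
# component considers every base within +/- refine_bp and moves to the
# position maximizing the total data log-likelihood (mixing weights held
# fixed) plus prior_weight log-likelihood units per positional-prior
# pseudo-count. Strong read evidence therefore overrides the prior, while
# positions with near-equivalent likelihood snap to explanatory sequence;
# remaining ties go to the lower coordinate. A read that falls outside the
# read-distribution support of every component is charged the
# distribution's probability floor (1e-9) rather than -Inf, so a stray
# distal read cannot veto an otherwise much better position.
refine_positions <- function(L, prior, st, refine_bp, prior_weight = 0.5,
                             tol = 1e-9) {
  M <- ncol(L)
  idx <- st$idx
  pi <- st$pi
  mix <- as.numeric(L[, idx, drop = FALSE] %*% pi)
  moved <- FALSE
  for (m in order(-pi)) {
    cand <- max(1L, idx[m] - refine_bp):min(M, idx[m] + refine_bp)
    cand <- setdiff(cand, idx[-m])
    base <- pmax(mix - pi[m] * L[, idx[m]], 0)
    X <- base + pi[m] * L[, cand, drop = FALSE]
    score <- colSums(log(pmax(X, pi[m] * 1e-9))) +
      prior_weight * prior[cand]
    best <- cand[which(score >= max(score) - tol)[1L]]  # tie: lower coord
    if (best != idx[m] &&
        score[match(best, cand)] > score[match(idx[m], cand)] + tol) {
      idx[m] <- best
      mix <- base + pi[m] * L[, best]
      moved <- TRUE
    }
  }
  o <- order(idx)
  list(moved = moved, st = list(idx = idx[o], pi = pi[o], trace = st$trace,
                                iter = st$iter, converged = st$converged))
}

empty_region_events <- function(region) {
  data.table::data.table(chrom = character(), pos = integer(),
                         strength = numeric())
}

# Penalized log posterior of the current model: data log-likelihood over
# reads with nonzero mixture probability plus the negative-Dirichlet term
# sum_m (alpha_m - alpha_s) log pi_m.
region_objective <- function(L, pi, alpha_s, alpha) {
  mix <- as.numeric(L %*% pi)
  sum(log(mix[mix > 0])) + sum((alpha - alpha_s) * log(pi))
}

# Collapse runs of surviving components separated by < merge_bp into single
# events: position of the largest strength (ties -> lower coordinate),
# strength = run total.
merge_close_components <- function(positions, strength, merge_bp) {
  if (length(positions) == 0L)
    return(list(pos = integer(), strength = numeric()))
  grp <- cumsum(c(0L, diff(positions) >= merge_bp))
  pos <- integer(0); str <- numeric(0)
  for (g in split(seq_along(positions), grp)) {
    best <- g[which.max(strength[g])]   # which.max takes the first maximum
    pos <- c(pos, positions[best])
    str <- c(str, sum(strength[g]))
  }
  list(pos = pos, strength = str)
}

#' Test called events for significance
#'
#' With a control sample, the read count of each event is compared with the
#' depth-scaled control count in a window around the event by an upper-tail
#' binomial test (success probability 1/2 on the combined count). Without a
#' control, an upper-tail Poisson test is used whose rate is the dynamic
#' maximum of the genome-wide rate and local rates estimated in 5 kb and
#' 10 kb centered windows, scaled to the event window. Only read counts of
#' events are used.
#'
#' @param events Event table with \code{strength}.
#' @param chip_reads ChIP read table.
#' @param control_reads Control read table or \code{NULL}.
#' @param genome_size Total genome length in bp.
#' @param window Event window width for control counting / rate scaling
#'   (default 201 bp, centered).
#' @return The event table with \code{p_value}, \code{q_value} (BH) and
#'   \code{fold} filled in (\code{fold = Inf} without control).
#' @export
test_significance <- function(events, chip_reads, control_reads = NULL,
                              genome_size, window = 201L) {
  if (genome_size <= 0) stop("zero-length genome")
  events <- data.table::as.data.table(events)
  if (nrow(events) == 0L) {
    events$p_value <- numeric(0); events$q_value <- numeric(0)
    events$fold <- numeric(0)
    return(events[])
  }
  half <- (window - 1L) %/% 2L
  n_chip <- round(events$strength)
  if (!is.null(control_reads) && nrow(control_reads) > 0L) {
    scale <- nrow(chip_reads) / nrow(control_reads)
    ctrl <- count_reads_near(control_reads, events$chrom, events$pos, half)
    scaled <- ctrl * scale
    n_tot <- n_chip + round(scaled)
    p <- stats::pbinom(n_chip - 1, n_tot, 0.5, lower.tail = FALSE)
    fold <- events$strength / (scaled + 1)
  } else {
    lam_g <- nrow(chip_reads) / genome_size
    c5 <- count_reads_near(chip_reads, events$chrom, events$pos, 2500L)
    c10 <- count_reads_near(chip_reads, events$chrom, events$pos, 5000L)
    lam <- pmax(lam_g, c5 / 5001, c10 / 10001) * window
    p <- stats::ppois(n_chip - 1, lam, lower.tail = FALSE)
    fold <- rep(Inf, nrow(events))
  }
  events$p_value <- pmin(1, pmax(p, .Machine$double.xmin))
  events$fold <- fold
  events$q_value <- bh_correct(events$p_value)
  events[]
}

# Number of reads with pos5 within +/- half bp of each (chrom, pos).
count_reads_near <- function(reads, chrom, pos, half) {
  out <- integer(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- sort(reads$pos5[reads$chrom == ch])
    out[sel] <- findInterval(pos[sel] + half, p) -
      findInterval(pos[sel] - half - 1L, p)
  }
  out
}

#' Benjamini-Hochberg correction
#'
#' Standard step-up q-values; a thin wrapper kept as the package's single
#' multiple-testing surface for event significance.
#'
#' @param p_values p-values in (0, 1].
#' @return q-values, same order as the input.
#' @export
bh_correct <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Call events over all regions
#'
#' Segments reads into regions, runs \code{\link{em_fit}} per region
#' (optionally with per-region positional priors) and concatenates the
#' called events sorted by (chrom, pos).
#'
#' @param reads Read table.
#' @param chrom_lengths Named chromosome lengths.
#' @param dist A \code{\link{read_dist}}.
#' @param priors Optional list of per-base alpha vectors, one per region
#'   (parallel to the segmentation), as built by
#'   \code{\link{region_priors}}.
#' @param alpha_s Sparse prior scalar or \code{NULL} for the per-region
#'   default \code{sqrt(#reads)}.
#' @param regions Optional pre-computed segmentation (so prior construction
#'   and calling share identical regions).
#' @param ... Passed to \code{\link{em_fit}}.
#' @return List with \code{events} and \code{regions}.
#' @export
call_events <- function(reads, chrom_lengths, dist, priors = NULL,
                        alpha_s = NULL, regions = NULL, ...) {
  if (is.null(regions)) regions <- segment_regions(reads, chrom_lengths)
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    prior <- if (is.null(priors)) NULL else priors[[i]]
    fit <- em_fit(regions[[i]], dist, prior = prior, alpha_s = alpha_s, ...)
    out[[i]] <- fit$events
  }
  events <- data.table::rbindlist(out)
  if (nrow(events) > 0L)
    data.table::setorderv(events, c("chrom", "pos"))
  list(events = events[], regions = regions)
}
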