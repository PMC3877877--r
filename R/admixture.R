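# Admixture painting: partition each chromosome of a test individual into
# "interval genotypes" over 2-3 source populations. Each state is an
# unordered pair of sources (which population each chromosome copy came
# from); per-SNV genotype likelihoods follow from the source reference-allele
# frequencies, and a dynamic program with a per-switch penalty chooses where
# the state changes along the chromosome.

#' Ancestry states for k source populations
#'
#' The unordered source pairs: 3 states for two sources --
#' (1,1), (1,2), (2,2) -- and 6 for three.
#'
#' @param n_sources 2 or 3
#' @return integer matrix with columns `a`, `b`, one row per state
#' @export
ancestry_states <- function(n_sources) {
  stopifnot(n_sources %in% c(2L, 3L))
  base <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  m <- if (n_sources == 2L) base else {
    rbind(base, c(1L, 3L), c(2L, 3L), c(3L, 3L))
  }
  colnames(m) <- c("a", "b")
  m
}

state_labels <- function(states) paste0(states[, 1L], "/", states[, 2L])

#' Log-probability of a genotype under an ancestry state
#'
#' With source reference-allele frequencies p_i, a homozygous-reference
#' genotype (2) has probability p_i^2 when both chromosome copies come from
#' source i, p_i p_j when one copy comes from each of i and j; heterozygous
#' and homozygous-variant genotypes follow the same product rule. Natural
#' logarithm.
#'
#' @param genotype 0, 1 or 2 reference-allele copies (-1 is rejected: callers
#'   skip uncalled sites)
#' @param state integer pair (i, j) of source indices
#' @param freqs numeric vector of per-source reference-allele frequencies at
#'   this SNV, clamped away from 0 and 1 by the caller
#' @return log probability
#' @export
emission_logprob <- function(genotype, state, freqs) {
  if (length(genotype) != 1L || !(genotype %in% c(0, 1, 2))) {
    stop("genotype must be a single value in {0, 1, 2}; uncalled sites are skipped",
         call. = FALSE)
  }
  p <- freqs[state[1L]]
  q <- freqs[state[2L]]
  pr <- switch(as.character(genotype),
    "2" = p * q,
    "1" = p * (1 - q) + q * (1 - p),
    "0" = (1 - p) * (1 - q)
  )
  log(pr)
}

# n x n_states emission log-prob matrix for genotypes in {0,1,2}
emission_matrix <- function(genotypes, freqs, states) {
  n <- length(genotypes)
  out <- matrix(NA_real_, n, nrow(states))
  for (s in seq_len(nrow(states))) {
    p <- freqs[, states[s, 1L]]
    q <- freqs[, states[s, 2L]]
    pr <- ifelse(genotypes == 2L, p * q,
          ifelse(genotypes == 1L, p * (1 - q) + q * (1 - p),
                 (1 - p) * (1 - q)))
    out[, s] <- log(pr)
  }
  out
}

# Per-site per-source reference-allele frequencies, clamped into
# [eps, 1 - eps] with eps = 1/(2n + 2), n = called alleles at the site
# (a site with no data collapses to the uninformative 0.5).
source_frequencies <- function(table, sources, mode = c("genotype", "reads")) {
  mode <- match.arg(mode)
  out <- matrix(NA_real_, n_snvs(table), length(sources))
  for (j in seq_along(sources)) {
    ac <- allele_counts(table, sources[[j]], mode)
    p <- ifelse(ac$n > 0, ac$a / ac$n, 0.5)
    eps <- 1 / (2 * ac$n + 2)
    out[, j] <- pmin(pmax(p, eps), 1 - eps)
  }
  colnames(out) <- vapply(sources, function(p) p$name, character(1))
  out
}

check_sources <- function(table, sources) {
  stopifnot(is.list(sources), length(sources) %in% c(2L, 3L))
  for (p in sources) check_pop(table, p)
  members <- unlist(lapply(sources, `[[`, "members"))
  if (anyDuplicated(members)) {
    stop("source populations must be disjoint", call. = FALSE)
  }
  invisible(sources)
}

#' Select ancestry-informative markers
#'
#' Keeps SNVs whose per-SNV F_ST between the source populations (the maximum
#' over pairs when there are three sources) exceeds `min_fst`, then
#' optionally thins to a minimum spacing with [sample_uniform()]. High-F_ST,
#' well-spaced markers make the painting both informative and closer to
#' independent.
#'
#' @param table an `snv_table`
#' @param sources list of 2 or 3 disjoint [specify_population()] objects
#' @param min_fst retain SNVs with F_ST strictly above this
#' @param min_spacing optional minimum bp spacing (NULL = no thinning)
#' @param estimator F_ST estimator, see [per_snp_fst()]
#' @param mode `"genotype"` or `"reads"`
#' @return the filtered `snv_table`
#' @export
select_aims <- function(table, sources, min_fst, min_spacing = NULL,
                        estimator = c("reich", "wright", "weir_cockerham"),
                        mode = c("genotype", "reads")) {
  check_sources(table, sources)
  estimator <- match.arg(estimator)
  mode <- match.arg(mode)
  pairs <- utils::combn(length(sources), 2L)
  fst <- matrix(NA_real_, n_snvs(table), ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    comp <- fst_site_components(table, sources[[pairs[1L, k]]],
                                sources[[pairs[2L, k]]], estimator, mode)
    v <- comp$num / comp$den
    if (estimator == "wright") v[comp$scoreable & comp$den == 0] <- 0
    fst[, k] <- v
  }
  best <- apply(fst, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  keep <- !is.na(best) & best > min_fst
  out <- subset_rows(table, keep)
  if (!is.null(min_spacing)) out <- sample_uniform(out, min_spacing)
  out
}

# DP over (SNV, state): maximize sum of emission log-probs minus
# switch_penalty per state change. Ties prefer staying in the previous
# state, then the lowest state index.
paint_dp <- function(emis, switch_penalty) {
  n <- nrow(emis)
  k <- ncol(emis)
  score <- matrix(-Inf, n, k)
  back <- matrix(NA_integer_, n, k)
  score[1L, ] <- emis[1L, ]
  if (n > 1L) {
    for (i in 2:n) {
      prev <- score[i - 1L, ]
      for (s in seq_len(k)) {
        v <- prev - switch_penalty * (seq_len(k) != s)
        m <- max(v)
        b <- if (v[s] == m) s else which(v == m)[1L]
        score[i, s] <- emis[i, s] + m
        back[i, s] <- b
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(score[n, ])  # ties: lowest state index
  if (n > 1L) {
    for (i in n:2) path[i - 1L] <- back[i, path[i]]
  }
  list(path = path, score = max(score[n, ]))
}

#' Paint one chromosome of a test individual
#'
#' Maximizes the summed genotype log-likelihood minus `switch_penalty` times
#' the number of ancestry-state switches, over all state sequences, by
#' dynamic programming with backtracking. Uncalled genotypes (-1) are
#' skipped: they emit nothing and consume no switch opportunity.
#'
#' @param genotypes integer vector of the individual's genotypes at the AIMs
#' @param positions 1-based bp positions, same length, increasing
#' @param freqs matrix of per-source reference-allele frequencies (one row
#'   per SNV, one column per source), already clamped away from 0/1
#' @param switch_penalty penalty per state change, in nats (>= 0)
#' @param chrom chromosome label for the output
#' @return data.frame of class `painted_segments`: chrom, start/end (first
#'   and last member-SNV positions), bp_start/bp_end (midpoint-bounded spans
#'   used for bp accounting), state label, source pair `a`/`b`, n_snvs,
#'   log_prob (summed emission log-probability); attribute `dp_score` holds
#'   the optimum objective
#' @export
paint_chromosome <- function(genotypes, positions, freqs, switch_penalty,
                             chrom = "chr") {
  stopifnot(switch_penalty >= 0, length(genotypes) == length(positions),
            nrow(freqs) == length(genotypes))
  use <- which(genotypes != -1L)
  if (!length(use)) {
    stop("no usable SNV: all genotypes are uncalled (-1)", call. = FALSE)
  }
  g <- genotypes[use]
  pos <- positions[use]
  fr <- freqs[use, , drop = FALSE]
  states <- ancestry_states(ncol(fr))
  emis <- emission_matrix(g, fr, states)
  dp <- paint_dp(emis, switch_penalty)
  r <- rle(dp$path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # bp spans: boundaries at the midpoint between the flanking SNVs of a switch
  bp_start <- pos[starts]
  bp_end <- pos[ends]
  if (length(starts) > 1L) {
    mids <- (pos[ends[-length(ends)]] + pos[starts[-1L]]) %/% 2L
    bp_end[-length(ends)] <- mids
    bp_start[-1L] <- mids + 1L
  }
  lp <- vapply(seq_along(starts), function(i) {
    rows <- starts[i]:ends[i]
    sum(emis[cbind(rows, dp$path[rows])])
  }, numeric(1))
  out <- data.frame(
    chrom = chrom,
    start = pos[starts], end = pos[ends],
    bp_start = bp_start, bp_end = bp_end,
    state = state_labels(states)[r$values],
    a = states[r$values, 1L], b = states[r$values, 2L],
    n_snvs = r$lengths, log_prob = lp,
    stringsAsFactors = FALSE
  )
  attr(out, "dp_score") <- dp$score
  attr(out, "n_sources") <- ncol(fr)
  class(out) <- c("painted_segments", "data.frame")
  out
}

#' Paint every chromosome of a test individual
#'
#' Computes source allele frequencies from the table, then runs
#' [paint_chromosome()] independently per chromosome (each autosome is
#' partitioned on its own).
#'
#' @param table an `snv_table` (typically AIMs from [select_aims()])
#' @param individual name of the test individual in `table`
#' @param sources list of 2 or 3 disjoint source populations
#' @param switch_penalty penalty per state change, in nats
#' @param mode allele-count mode for source frequencies
#' @return `painted_segments` data.frame spanning all chromosomes
#' @export
paint_genome <- function(table, individual, sources, switch_penalty,
                         mode = c("genotype", "reads")) {
  check_sources(table, sources)
  mode <- match.arg(mode)
  freqs <- source_frequencies(table, sources, mode)
  g <- genotype_matrix(table, individual)[, 1L]
  d <- table$data
  segs <- list()
  for (ch in unique(d$chrom)) {
    i <- which(d$chrom == ch)
    if (!any(g[i] != -1L)) next
    segs[[ch]] <- paint_chromosome(g[i], d$pos[i], freqs[i, , drop = FALSE],
                                   switch_penalty, chrom = ch)
  }
  if (!length(segs)) stop("no usable SNV for individual ", individual, call. = FALSE)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  attr(out, "n_sources") <- length(sources)
  class(out) <- c("painted_segments", "data.frame")
  out
}

#' Genome-wide ancestry proportions from a painting
#'
#' Each segment's bp span (bp_end - bp_start + 1) is credited wholly to
#' source i for state (i,i) and half to each of i and j for state (i,j);
#' fractions are normalized over the total span. SNV-count weighting is
#' reported alongside, since either convention is defensible.
#'
#' @param segments a `painted_segments` data.frame
#' @param n_sources number of source populations (default from attribute)
#' @return list with numeric vectors `by_bp` and `by_snv`, each summing to 1
#' @export
ancestry_proportions <- function(segments, n_sources = NULL) {
  if (!nrow(segments)) stop("empty painting", call. = FALSE)
  if (is.null(n_sources)) n_sources <- attr(segments, "n_sources")
  stopifnot(!is.null(n_sources))
  tally <- function(w) {
    acc <- numeric(n_sources)
    for (i in seq_len(nrow(segments))) {
      a <- segments$a[i]
      b <- segments$b[i]
      if (a == b) acc[a] <- acc[a] + w[i]
      else {
        acc[a] <- acc[a] + w[i] / 2
        acc[b] <- acc[b] + w[i] / 2
      }
    }
    stats::setNames(acc / sum(acc), paste0("source", seq_len(n_sources)))
  }
  list(by_bp = tally(segments$bp_end - segments$bp_start + 1),
       by_snv = tally(segments$n_snvs))
}
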