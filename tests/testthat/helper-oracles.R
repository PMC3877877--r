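# Independent brute-force oracles shared across the suite. Each recomputes
# a quantity by enumeration or direct transcription, never by calling the
# code path under test.

# All maximal-scoring subsequences via cumulative sums: [i, j] qualifies iff
# the cumulative score before i is the strict unique minimum and the score
# through j the strict unique maximum over the window, and no longer
# qualifying run contains it.
max_segments_oracle <- function(x) {
  n <- length(x)
  C <- c(0, cumsum(x))
  cand <- list()
  for (i in seq_len(n)) {
    mn <- mx <- C[i]
    mn_ct <- mx_ct <- 1L
    for (j in i:n) {
      v <- C[j + 1]
      if (v < mn) { mn <- v; mn_ct <- 1L } else if (v == mn) mn_ct <- mn_ct + 1L
      if (v > mx) { mx <- v; mx_ct <- 1L } else if (v == mx) mx_ct <- mx_ct + 1L
      if (C[i] == mn && mn_ct == 1L && v == mx && mx_ct == 1L) {
        cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  }
  m <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(m)), function(k) {
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           (m[, 1] != m[k, 1] | m[, 2] != m[k, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2],
             score = C[m[, 2] + 1] - C[m[, 1]])
}

# Exhaustive maximum of the painting objective over all state paths:
# sum of emission log-probs minus lambda per state change.
paint_score_oracle <- function(emis, lambda) {
  n <- nrow(emis)
  k <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  obj <- numeric(nrow(paths))
  for (t in seq_len(n)) {
    obj <- obj + emis[t, ][paths[, t]]
    if (t > 1L) obj <- obj - lambda * (paths[, t] != paths[, t - 1L])
  }
  max(obj)
}

# objective value of a concrete state path
paint_path_objective <- function(emis, path, lambda) {
  sum(emis[cbind(seq_along(path), path)]) - lambda * sum(diff(path) != 0)
}

# Reich F_ST components, scalar transcription
reich_oracle <- function(a1, n1, a2, n2) {
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  N <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  list(N = N, D = N + h1 + h2)
}

# brute-force pi at one site: mean pairwise difference over all allele pairs
pi_site_oracle <- function(a, n) {
  alleles <- c(rep(1L, a), rep(0L, n - a))
  pairs <- utils::combn(n, 2)
  mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
}

# two-tailed Fisher p by exhaustive hypergeometric enumeration over all
# feasible 2x2 tables with the observed margins
fisher_two_tailed_oracle <- function(k, K, n, N) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  support <- lo:hi
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-bp agreement between a painting and the simulated truth tracts,
# evaluated on a grid of points inside the painted spans
painting_accuracy <- function(segs, truth, step = 1000) {
  hits <- 0L
  total <- 0L
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, ]
    tr <- truth[truth$chrom == ch, ]
    for (i in seq_len(nrow(s))) {
      pts <- seq(s$bp_start[i], s$bp_end[i], by = step)
      j <- findInterval(pts, tr$start)
      ok <- j >= 1 & pts <= tr$end[pmax(j, 1)]
      match <- ok & tr$a[pmax(j, 1)] == s$a[i] & tr$b[pmax(j, 1)] == s$b[i]
      hits <- hits + sum(match)
      total <- total + length(pts)
    }
  }
  hits / total
}
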