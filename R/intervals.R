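# Window-free detection of high-scoring SNV runs: subtract a shift from each
# per-SNV score, then report all maximal-scoring subsequences -- runs whose
# shifted total cannot be increased by adding or trimming SNVs at either end.

#' All maximal-scoring subsequences of a score vector
#'
#' Linear-time stack algorithm. A reported run has positive total; all its
#' proper sub-runs score strictly less, and it is contained in no longer run
#' with that property. Runs are disjoint.
#'
#' @param x numeric vector of (already shifted) scores
#' @return data.frame with `start`, `end` (indices into `x`) and `score`
#' @export
ruzzo_tompa <- function(x) {
  stopifnot(is.numeric(x), !anyNA(x))
  n <- length(x)
  # parallel stacks: cumulative score before start (L), through end (R),
  # start and end indices
  Ls <- Rs <- numeric(n)
  ss <- es <- integer(n)
  top <- 0L
  cum <- 0
  for (k in seq_len(n)) {
    if (x[k] <= 0) {
      cum <- cum + x[k]
      next
    }
    Lk <- cum
    cum <- cum + x[k]
    Rk <- cum
    sk <- k
    ek <- k
    repeat {
      j <- top
      while (j >= 1L && Ls[j] >= Lk) j <- j - 1L
      if (j == 0L || Rs[j] >= Rk) {
        top <- top + 1L
        Ls[top] <- Lk; Rs[top] <- Rk; ss[top] <- sk; es[top] <- ek
        break
      }
      # merge I_j with the current candidate and retry
      Lk <- Ls[j]
      sk <- ss[j]
      top <- j - 1L
    }
  }
  idx <- seq_len(top)
  data.frame(start = ss[idx], end = es[idx], score = Rs[idx] - Ls[idx])
}

#' Maximal-scoring SNV intervals of a score column
#'
#' Subtracts `shift` from the chosen per-SNV score column and finds, per
#' chromosome, all maximal runs of positive shifted total. Interval
#' coordinates are the positions of the first and last member SNV. Results
#' are ranked by descending score; ties go to the leftmost (table order),
#' then shortest, interval. SNVs with NA scores are dropped before
#' segmentation. Raising the shift yields fewer and shorter intervals.
#'
#' @param table an `snv_table` with a numeric score column
#' @param column name of the score column (e.g. appended by
#'   [per_snp_fst()] or a homozygosity computation)
#' @param shift the shift value subtracted from every score; alternatively
#'   use [percentile_shift()] to derive it from a percentile
#' @return data.frame of class `scored_intervals`: chrom, start, end, score,
#'   n_snvs, rank (plus row indices `first_idx` / `last_idx` into the table)
#' @export
max_scoring_segments <- function(table, column, shift) {
  if (!column %in% names(table$data)) {
    stop("no such score column: ", column, call. = FALSE)
  }
  scores <- table$data[[column]]
  keep <- which(!is.na(scores))
  out <- list()
  d <- table$data
  for (ch in unique(d$chrom[keep])) {
    i <- keep[d$chrom[keep] == ch]
    seg <- ruzzo_tompa(scores[i] - shift)
    if (!nrow(seg)) next
    out[[ch]] <- data.frame(
      chrom = ch,
      start = d$pos[i[seg$start]],
      end = d$pos[i[seg$end]],
      score = seg$score,
      n_snvs = seg$end - seg$start + 1L,
      first_idx = i[seg$start],
      last_idx = i[seg$end],
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               score = numeric(), n_snvs = integer(),
               first_idx = integer(), last_idx = integer())
  }
  rownames(res) <- NULL
  o <- order(-res$score, res$first_idx, res$n_snvs)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  res$rank <- seq_len(nrow(res))
  class(res) <- c("scored_intervals", "data.frame")
  res
}

#' Shift value at a score percentile
#'
#' Converts "set the shift at, say, the 90th percentile" into a concrete
#' shift by linear interpolation between order statistics; at least
#' `percentile` of the shifted scores are then <= 0.
#'
#' @param scores numeric scores (NAs dropped)
#' @param percentile in (0, 1), e.g. 0.9
#' @return the shift value
#' @export
percentile_shift <- function(scores, percentile) {
  stopifnot(percentile > 0, percentile < 1)
  unname(stats::quantile(scores, percentile, na.rm = TRUE, type = 7))
}

#' Empirical significance of observed intervals by score shuffling
#'
#' Shuffles the per-SNV scores (positions fixed) `n_shuffles` times, records
#' the best interval score of each shuffle, and takes the highest as the
#' cutoff. The empirical p of an observed interval with score s is
#' `(1 + #\{shuffles with best >= s\}) / (n_shuffles + 1)` -- never exactly 0.
#' Assumes independent scores. Shuffling is genome-wide by default;
#' `within_chrom = TRUE` permutes within each chromosome instead.
#'
#' @inheritParams max_scoring_segments
#' @param n_shuffles number of permutations (>= 1)
#' @param seed integer RNG seed (the caller's RNG state is untouched)
#' @param within_chrom permute scores within chromosomes only
#' @return list with `intervals` (observed intervals plus `empirical_p`),
#'   `cutoff` (highest best-of-shuffle score), `best_scores`, `n_shuffles`,
#'   `seed`
#' @export
shuffle_significance <- function(table, column, shift, n_shuffles = 100L,
                                 seed = 1L, within_chrom = FALSE) {
  stopifnot(n_shuffles >= 1)
  observed <- max_scoring_segments(table, column, shift)
  scores <- table$data[[column]]
  chrom <- table$data$chrom
  best <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    perm <- if (within_chrom) {
      stats::ave(scores, chrom, FUN = sample)
    } else {
      sample(scores)
    }
    tmp <- table
    tmp$data[[column]] <- perm
    seg <- max_scoring_segments(tmp, column, shift)
    if (nrow(seg)) max(seg$score) else 0
  }, numeric(1)))
  observed$empirical_p <- vapply(observed$score, function(s) {
    (1 + sum(best >= s)) / (n_shuffles + 1)
  }, numeric(1))
  list(intervals = observed, cutoff = if (length(best)) max(best) else 0,
       best_scores = best, n_shuffles = n_shuffles, seed = seed)
}

#' Read a gene annotation table
#'
#' Tab-delimited with a header naming at least `gene`, `chrom`, `start`,
#' `end` (1-based inclusive); a `strand` column is carried through if
#' present.
#'
#' @param path file path
#' @return data.frame of gene spans
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(g))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  g
}

#' Genes intersecting scored intervals
#'
#' Reports a gene for an interval when their closed 1-based spans overlap by
#' at least 1 bp on the same chromosome.
#'
#' @param intervals a `scored_intervals` data.frame (or any data.frame with
#'   chrom/start/end)
#' @param genes a gene table as from [read_gene_table()]
#' @return data.frame pairing interval rank/coordinates with gene names;
#'   zero rows when nothing overlaps
#' @export
intersect_genes <- function(intervals, genes) {
  empty <- data.frame(rank = integer(), chrom = character(), start = integer(),
                      end = integer(), score = numeric(), gene = character())
  if (!nrow(intervals) || !nrow(genes)) return(empty)
  gr_i <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start, intervals$end))
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_i, gr_g)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  if (!length(qi)) return(empty)
  rk <- if ("rank" %in% names(intervals)) intervals$rank else seq_len(nrow(intervals))
  sc <- if ("score" %in% names(intervals)) intervals$score else NA_real_
  data.frame(
    rank = rk[qi], chrom = intervals$chrom[qi], start = intervals$start[qi],
    end = intervals$end[qi], score = sc[qi], gene = genes$gene[si],
    stringsAsFactors = FALSE
  )
}

#' Export intervals (or any 1-based spans) as BED
#'
#' Converts 1-based inclusive coordinates to BED's 0-based half-open form.
#'
#' @param x data.frame with chrom, start, end and optionally score
#' @param path output path
#' @param names optional feature names (default `region_<i>`)
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path, names = NULL) {
  if (is.null(names)) names <- paste0("region_", seq_len(nrow(x)))
  score <- if ("score" %in% colnames(x)) x$score else 0
  bed <- data.frame(x$chrom, x$start - 1L, x$end, names, score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
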