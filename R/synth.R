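# Synthetic-data generators: populations under a Balding-Nichols drift
# model, admixed individuals with known ancestry tracts, pooled read counts,
# and the small pooled-counts fixture used in the worked sweep example.
# Everything is reproducible from an explicit seed.

#' Simulate differentiated populations
#'
#' Ancestral reference-allele frequencies are drawn Uniform(0.05, 0.95) per
#' SNV; each population's frequency is Beta-distributed around the ancestral
#' value with variance scaled by its drift parameter F (Balding-Nichols), so
#' F = 0 reproduces the ancestral frequency exactly and larger F means more
#' differentiation. Genotypes are Binomial(2, p) reference-allele counts.
#' With `depth_mean` set, pooled read counts are layered on via
#' [simulate_read_counts()] and a gd_snp table is returned; otherwise a
#' gd_genotype table.
#'
#' @param n_pops number of populations
#' @param n_per_pop diploid individuals per population
#' @param n_snvs total SNV count, split evenly over chromosomes
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param F drift parameter per population in [0, 1); recycled
#' @param depth_mean mean read depth (NULL = genotype-only table)
#' @param error_rate sequencing error rate in [0, 0.5)
#' @param seed integer RNG seed
#' @return list: `table` (an `snv_table`), `freqs` (true per-population
#'   frequency matrix), `pops` (list of [specify_population()] objects),
#'   `config`
#' @export
simulate_populations <- function(n_pops = 2, n_per_pop = 10, n_snvs = 1000,
                                 n_chroms = 1, chrom_length = 1e6,
                                 F = 0.1, depth_mean = NULL,
                                 error_rate = 0.01, seed = 1) {
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_snvs >= 1, n_chroms >= 1,
            all(F >= 0), all(F < 1), error_rate >= 0, error_rate < 0.5)
  F <- rep_len(F, n_pops)
  with_seed(seed, {
    per_chrom <- diff(round(seq(0, n_snvs, length.out = n_chroms + 1)))
    chrom <- rep(paste0("chr", seq_len(n_chroms)), per_chrom)
    pos <- unlist(lapply(per_chrom, function(m) {
      sort(sample.int(chrom_length, m))
    }))
    alleles <- t(vapply(seq_len(n_snvs), function(i) {
      sample(c("A", "C", "G", "T"), 2L)
    }, character(2)))
    anc <- stats::runif(n_snvs, 0.05, 0.95)
    freqs <- matrix(NA_real_, n_snvs, n_pops)
    for (j in seq_len(n_pops)) {
      freqs[, j] <- if (F[j] == 0) anc else {
        stats::rbeta(n_snvs, anc * (1 - F[j]) / F[j],
                     (1 - anc) * (1 - F[j]) / F[j])
      }
    }
    pop_names <- paste0("pop", seq_len(n_pops))
    ind_names <- as.vector(t(outer(pop_names, seq_len(n_per_pop),
                                   paste, sep = "_")))
    geno <- matrix(NA_integer_, n_snvs, n_pops * n_per_pop)
    for (j in seq_len(n_pops)) {
      for (i in seq_len(n_per_pop)) {
        geno[, (j - 1L) * n_per_pop + i] <- stats::rbinom(n_snvs, 2L, freqs[, j])
      }
    }
    site <- data.frame(chrom = chrom, pos = pos, ref = alleles[, 1L],
                       var = alleles[, 2L], qual = -1,
                       stringsAsFactors = FALSE)
    if (is.null(depth_mean)) {
      table <- build_snv_table(site, geno, ind_names, "gd_genotype")
    } else {
      k <- ncol(geno)
      samples <- matrix(-1, n_snvs, 4L * k)
      for (j in seq_len(k)) {
        rc <- simulate_read_counts(geno[, j], depth_mean, error_rate)
        samples[, 4L * j - 3L] <- rc$ref
        samples[, 4L * j - 2L] <- rc$var
        samples[, 4L * j - 1L] <- geno[, j]
      }
      table <- build_snv_table(site, samples, ind_names, "gd_snp")
    }
    pops <- lapply(seq_len(n_pops), function(j) {
      specify_population(table, ind_names[(j - 1L) * n_per_pop + seq_len(n_per_pop)],
                         pop_names[j])
    })
    list(table = table, freqs = freqs, pops = pops,
         config = list(n_pops = n_pops, n_per_pop = n_per_pop,
                       n_snvs = n_snvs, n_chroms = n_chroms,
                       chrom_length = chrom_length, F = F,
                       depth_mean = depth_mean, error_rate = error_rate,
                       seed = seed))
  })
}

#' Simulate pooled read counts for genotypes
#'
#' Depth is Poisson(`depth_mean`); each read reports the reference allele
#' with probability `(g/2)(1 - e) + (1 - g/2)e` for genotype g and error
#' rate e.
#'
#' @param genotype vector of genotypes in \{0, 1, 2\}
#' @param depth_mean Poisson mean depth (> 0)
#' @param error_rate per-read error rate in [0, 0.5)
#' @param seed optional seed (NULL = use the current RNG stream)
#' @return list of integer vectors `ref`, `var`
#' @export
simulate_read_counts <- function(genotype, depth_mean, error_rate = 0,
                                 seed = NULL) {
  stopifnot(depth_mean > 0, all(genotype %in% c(0L, 1L, 2L)))
  draw <- function() {
    depth <- stats::rpois(length(genotype), depth_mean)
    p_ref <- (genotype / 2) * (1 - error_rate) + (1 - genotype / 2) * error_rate
    ref <- stats::rbinom(length(genotype), depth, p_ref)
    list(ref = ref, var = depth - ref)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate an admixed individual with known ancestry tracts
#'
#' Each of the two chromosome copies is tiled independently with ancestry
#' tracts of Exponential(`mean_tract_bp`) length whose source is drawn from
#' `mix`; the copy's allele at each SNV is Bernoulli with that source's true
#' reference-allele frequency, and the diploid genotype is the sum of the
#' copies. The realized truth is returned as interval genotypes (unordered
#' source pairs) tiling each chromosome, adjacent tracts differing in state.
#'
#' @param table the `snv_table` whose SNV coordinates the individual is
#'   genotyped at
#' @param freqs true per-source reference-allele frequency matrix (one row
#'   per SNV of `table`)
#' @param mix per-source ancestry proportions, summing to 1
#' @param mean_tract_bp mean ancestry-tract length in bp
#' @param seed integer RNG seed
#' @return list: `genotypes` (integer vector along the table's SNVs),
#'   `truth` (data.frame chrom, start, end, a, b tiling each chromosome),
#'   `mix`, `seed`
#' @export
simulate_admixed <- function(table, freqs, mix, mean_tract_bp, seed = 1) {
  stopifnot(abs(sum(mix) - 1) < 1e-8, mean_tract_bp > 0,
            nrow(freqs) == n_snvs(table))
  k <- length(mix)
  d <- table$data
  with_seed(seed, {
    genotypes <- integer(nrow(d))
    truth <- list()
    for (ch in unique(d$chrom)) {
      i <- which(d$chrom == ch)
      L <- max(d$pos[i])
      # tract breakpoints per chromosome copy
      copy_tracts <- lapply(1:2, function(cp) {
        ends <- numeric(0)
        at <- 0
        while (at < L) {
          at <- at + stats::rexp(1, 1 / mean_tract_bp)
          ends <- c(ends, min(ceiling(at), L))
        }
        data.frame(end = unique(ends),
                   src = sample.int(k, length(unique(ends)),
                                    replace = TRUE, prob = mix))
      })
      src_at <- function(tr, pos) tr$src[findInterval(pos, tr$end + 1L) + 1L]
      s1 <- src_at(copy_tracts[[1L]], d$pos[i])
      s2 <- src_at(copy_tracts[[2L]], d$pos[i])
      a1 <- stats::rbinom(length(i), 1L, freqs[cbind(i, s1)])
      a2 <- stats::rbinom(length(i), 1L, freqs[cbind(i, s2)])
      genotypes[i] <- a1 + a2
      # merge both copies' breakpoints into diploid interval genotypes
      cuts <- sort(unique(c(copy_tracts[[1L]]$end, copy_tracts[[2L]]$end, L)))
      starts <- c(1L, utils::head(cuts, -1L) + 1L)
      keep <- starts <= cuts
      starts <- starts[keep]
      cuts <- cuts[keep]
      mids <- (starts + cuts) / 2
      pa <- src_at(copy_tracts[[1L]], mids)
      pb <- src_at(copy_tracts[[2L]], mids)
      st <- cbind(pmin(pa, pb), pmax(pa, pb))
      # collapse adjacent tracts with equal diploid state
      key <- paste(st[, 1L], st[, 2L])
      r <- rle(key)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1L
      truth[[ch]] <- data.frame(
        chrom = ch, start = starts[starts_idx], end = cuts[ends_idx],
        a = st[starts_idx, 1L], b = st[starts_idx, 2L],
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(genotypes = genotypes, truth = truth, mix = mix, seed = seed)
  })
}

#' Append an individual to a gd_genotype table
#'
#' Inserts the new genotype column at the end of the sample block, before
#' any chained score columns.
#'
#' @param table an `snv_table` in gd_genotype mode
#' @param name new individual's name
#' @param genotypes integer vector in \{-1, 0, 1, 2\}, one per SNV
#' @return the extended `snv_table`
#' @export
add_individual <- function(table, name, genotypes) {
  if (table$mode != "gd_genotype") {
    stop("add_individual supports gd_genotype tables", call. = FALSE)
  }
  stopifnot(length(genotypes) == n_snvs(table))
  if (name %in% table$individuals$name) {
    stop("individual already present: ", name, call. = FALSE)
  }
  d <- table$data
  at <- FIXED_COLS + nrow(table$individuals)
  d <- cbind(d[, seq_len(at), drop = FALSE],
             stats::setNames(data.frame(as.integer(genotypes)), name),
             d[, setdiff(seq_along(d), seq_len(at)), drop = FALSE])
  ind <- rbind(table$individuals,
               data.frame(name = name, first_column = at + 1L, alias = name,
                          stringsAsFactors = FALSE))
  new_snv_table(d, ind, "gd_genotype", table$extra)
}

#' The pooled-counts sweep fixture
#'
#' A single-chromosome gd_snp table with one pooled sample: a run of 10
#' fixed SNVs (30 reference reads, 0 variant), a spacer of heterozygous
#' SNVs (15/15), then a run of 100 fixed SNVs. Aggregating the pool and
#' scoring homozygosity gives 1.0 at fixed sites; at shift 0.9 the two runs
#' form maximal intervals scoring 1.0 and 10.0, the 100-SNV run ranking
#' first.
#'
#' @param spacing bp between consecutive SNVs
#' @return an `snv_table` in gd_snp mode
#' @export
chicken_toy_table <- function(spacing = 1000L) {
  counts <- rbind(
    matrix(rep(c(30L, 0L), each = 10L), ncol = 2),
    matrix(rep(c(15L, 15L), each = 5L), ncol = 2),
    matrix(rep(c(30L, 0L), each = 100L), ncol = 2)
  )
  n <- nrow(counts)
  geno <- ifelse(counts[, 2L] == 0L, 2L, 1L)
  samples <- cbind(counts[, 1L], counts[, 2L], geno, rep(-1, n))
  site <- data.frame(chrom = "chr1", pos = seq_len(n) * spacing,
                     ref = "A", var = "G", qual = -1,
                     stringsAsFactors = FALSE)
  build_snv_table(site, samples, "pool", "gd_snp")
}
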