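#' Allele frequency from counts
#'
#' @param a reference-allele count (0 <= a <= n)
#' @param n total allele count (> 0)
#' @return a / n
#' @export
allele_frequency <- function(a, n) {
  if (any(n <= 0)) stop("undefined frequency: total allele count is 0", call. = FALSE)
  stopifnot(all(a >= 0), all(a <= n))
  a / n
}

#' Pooled homozygosity score
#'
#' The sum of squared allele frequencies, `(r^2 + v^2) / (r + v)^2`, computed
#' from pooled reference and variant totals. Equals 1 - heterozygosity:
#' 1 when one allele is absent, 0.5 at r = v, symmetric in (r, v).
#'
#' @param ref_total,var_total pooled allele (or read) counts, both >= 0
#' @return score in [0.5, 1]; vectorized
#' @export
homozygosity_score <- function(ref_total, var_total) {
  tot <- ref_total + var_total
  if (any(tot <= 0)) stop("undefined homozygosity: zero total count", call. = FALSE)
  (ref_total^2 + var_total^2) / tot^2
}

# Per-site allele counts for a population.
# mode "genotype": a = reference copies over called members, n = 2 x called.
# mode "reads":   a = summed ref reads, n = summed total reads (pooled data).
allele_counts <- function(table, pop, mode = c("genotype", "reads")) {
  mode <- match.arg(mode)
  check_pop(table, pop)
  if (mode == "genotype") {
    g <- genotype_matrix(table, pop$members)
    called <- g != -1L
    list(a = rowSums(g * called), n = 2L * rowSums(called))
  } else {
    rm_ <- read_matrices(table, pop$members)
    list(a = rowSums(pmax(rm_$ref, 0L)),
         n = rowSums(pmax(rm_$ref, 0L)) + rowSums(pmax(rm_$var, 0L)))
  }
}

#' Nucleotide diversity (pi) and Watterson's theta
#'
#' Per site, `pi_site = 2 a (n - a) / (n (n - 1))` with `n` the called allele
#' count and `a` the reference-allele count -- the mean pairwise difference
#' among the sampled alleles. `pi` is the sum over sites. `theta_w` counts
#' sites segregating within the population, each contributing
#' `1 / a_n(n_site)` with `a_n(n) = sum_{i=1}^{n-1} 1/i` evaluated at that
#' site's own called-allele count (sites differing in missingness therefore
#' use their own harmonic factor). Sites with fewer than two called alleles
#' contribute to neither statistic. If a sequence length `L` is supplied both
#' sums are also reported per bp.
#'
#' @inheritParams filter_snvs
#' @param L optional sequence length (bp) for per-site normalization
#' @param mode `"genotype"` (default) or `"reads"` for pooled samples
#' @return list with `pi`, `theta`, `n_segregating`, `per_site` data.frame,
#'   and `pi_per_bp` / `theta_per_bp` when `L` is given
#' @export
nucleotide_diversity <- function(table, pop, L = NULL,
                                 mode = c("genotype", "reads")) {
  ac <- allele_counts(table, pop, match.arg(mode))
  usable <- ac$n >= 2L
  if (!any(usable)) {
    stop("no site has two or more called alleles in population '",
         pop$name, "'", call. = FALSE)
  }
  a <- ac$a[usable]
  n <- ac$n[usable]
  pi_site <- 2 * a * (n - a) / (n * (n - 1))
  seg <- a > 0L & a < n
  harm <- vapply(n, function(k) sum(1 / seq_len(k - 1L)), numeric(1))
  theta_site <- ifelse(seg, 1 / harm, 0)
  per_site <- data.frame(
    chrom = table$data$chrom[usable], pos = table$data$pos[usable],
    n_alleles = n, ref_count = a, pi = pi_site, theta = theta_site)
  out <- list(pi = sum(pi_site), theta = sum(theta_site),
              n_segregating = sum(seg), per_site = per_site)
  if (!is.null(L)) {
    stopifnot(L > 0)
    out$pi_per_bp <- out$pi / L
    out$theta_per_bp <- out$theta / L
  }
  out
}

# --- F_ST estimators on per-site counts ------------------------------------
# Each returns numerator and denominator so the overall statistic can be the
# ratio of sums across sites rather than the mean of per-site ratios.

fst_wright_components <- function(a1, n1, a2, n2) {
  p1 <- a1 / n1
  p2 <- a2 / n2
  pbar <- (p1 + p2) / 2
  num <- (p1 - p2)^2 / 4        # population variance of (p1, p2)
  den <- pbar * (1 - pbar)
  list(num = num, den = den)
}

fst_reich_components <- function(a1, n1, a2, n2) {
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  N <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  D <- N + h1 + h2
  list(num = N, den = D)
}

# Weir & Cockerham (1984) two-allele variance components for r = 2
# populations, from called-individual counts, reference-allele frequencies
# and observed heterozygote proportions. Returns a (among-population) and
# a + b + c (total); theta-hat = a / (a + b + c).
fst_wc_components <- function(nind1, p1, h1, nind2, p2, h2) {
  r <- 2
  nbar <- (nind1 + nind2) / 2
  nc <- (r * nbar - (nind1^2 + nind2^2) / (r * nbar)) / (r - 1)
  pbar <- (nind1 * p1 + nind2 * p2) / (r * nbar)
  s2 <- (nind1 * (p1 - pbar)^2 + nind2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nind1 * h1 + nind2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(num = a, den = a + b + cc)
}

fst_site_components <- function(table, pop1, pop2,
                                estimator = c("reich", "wright", "weir_cockerham"),
                                mode = c("genotype", "reads")) {
  estimator <- match.arg(estimator)
  mode <- match.arg(mode)
  n <- n_snvs(table)
  num <- rep(NA_real_, n)
  den <- rep(NA_real_, n)
  if (estimator == "weir_cockerham") {
    if (mode != "genotype") {
      stop("the Weir-Cockerham estimator needs per-individual genotypes",
           call. = FALSE)
    }
    stat_pop <- function(pop) {
      g <- genotype_matrix(table, pop$members)
      called <- g != -1L
      nind <- rowSums(called)
      list(nind = nind,
           p = ifelse(nind > 0, rowSums(g * called) / (2 * nind), NA_real_),
           h = ifelse(nind > 0, rowSums((g == 1L) * called) / nind, NA_real_))
    }
    s1 <- stat_pop(pop1)
    s2 <- stat_pop(pop2)
    ok <- s1$nind >= 1L & s2$nind >= 1L & (s1$nind + s2$nind) > 2L
    if (any(ok)) {
      comp <- fst_wc_components(s1$nind[ok], s1$p[ok], s1$h[ok],
                                s2$nind[ok], s2$p[ok], s2$h[ok])
      num[ok] <- comp$num
      den[ok] <- comp$den
    }
  } else {
    c1 <- allele_counts(table, pop1, mode)
    c2 <- allele_counts(table, pop2, mode)
    ok <- if (estimator == "reich") c1$n >= 2L & c2$n >= 2L
          else c1$n >= 1L & c2$n >= 1L
    if (any(ok)) {
      f <- if (estimator == "reich") fst_reich_components else fst_wright_components
      comp <- f(c1$a[ok], c1$n[ok], c2$a[ok], c2$n[ok])
      num[ok] <- comp$num
      den[ok] <- comp$den
    }
  }
  list(num = num, den = den, scoreable = !is.na(num))
}

#' Per-SNV F_ST between two populations
#'
#' Appends a per-SNV fixation-index column. Three estimators: `"wright"`
#' (the original definition -- variance of the two allele frequencies over
#' its limiting value, defined 0 when the mean frequency is 0 or 1, always
#' in [0, 1]); `"reich"` (the unbiased moment estimator N/D with
#' `h_i = a_i (n_i - a_i) / (n_i (n_i - 1))`,
#' `N = (a1/n1 - a2/n2)^2 - h1/n1 - h2/n2`, `D = N + h1 + h2`; can be
#' negative, 1 when the populations are fixed for opposite alleles; needs at
#' least two called alleles per population); `"weir_cockerham"` (the 1984
#' two-population variance-components estimator, genotype mode only).
#' Unscoreable sites get NA; their count is attached as attribute
#' `n_unscoreable`.
#'
#' @param table an `snv_table`
#' @param pop1,pop2 the two populations
#' @param estimator one of `"reich"`, `"wright"`, `"weir_cockerham"`
#' @param mode `"genotype"` (default) or `"reads"` for pooled counts
#' @param column name for the appended column (default
#'   `fst.<pop1>.<pop2>`)
#' @return the table with the score column appended
#' @export
per_snp_fst <- function(table, pop1, pop2,
                        estimator = c("reich", "wright", "weir_cockerham"),
                        mode = c("genotype", "reads"), column = NULL) {
  estimator <- match.arg(estimator)
  comp <- fst_site_components(table, pop1, pop2, estimator, mode)
  val <- comp$num / comp$den
  if (estimator == "wright") {
    val[comp$scoreable & comp$den == 0] <- 0
  }
  if (is.null(column)) column <- paste("fst", pop1$name, pop2$name, sep = ".")
  out <- add_column(table, column, val)
  attr(out, "n_unscoreable") <- sum(!comp$scoreable)
  out
}

#' Overall F_ST between two populations
#'
#' The ratio of summed per-site numerator and denominator components across
#' scoreable SNVs (for Reich, `sum(N) / sum(D)`) -- not the mean of per-site
#' ratios.
#'
#' @inheritParams per_snp_fst
#' @return scalar estimate
#' @export
overall_fst <- function(table, pop1, pop2,
                        estimator = c("reich", "wright", "weir_cockerham"),
                        mode = c("genotype", "reads")) {
  estimator <- match.arg(estimator)
  comp <- fst_site_components(table, pop1, pop2, estimator, mode)
  if (!any(comp$scoreable)) {
    stop("no scoreable SNV for overall F_ST", call. = FALSE)
  }
  den <- sum(comp$den[comp$scoreable])
  if (den == 0) stop("undefined overall F_ST: denominator sum is 0", call. = FALSE)
  sum(comp$num[comp$scoreable]) / den
}

#' Locus-specific branch length
#'
#' The branch length of population A in the three-population tree, from the
#' three pairwise fixation indices: `(f_ab + f_ac - f_bc) / 2`. Negative
#' values are reported as-is. LSBL_A + LSBL_B = f_ab by construction.
#'
#' @param f_ab,f_ac,f_bc pairwise F_ST values for (A,B), (A,C), (B,C);
#'   vectorized
#' @return LSBL of A
#' @export
lsbl <- function(f_ab, f_ac, f_bc) {
  (f_ab + f_ac - f_bc) / 2
}
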