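# Small in-code fixture builders shared across the suite.

# gd_genotype table from a genotype matrix (rows = SNVs, cols = individuals)
geno_table <- function(geno, pos = NULL, chrom = NULL, names = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(names)) names <- paste0("ind", seq_len(ncol(geno)))
  site <- data.frame(chrom = chrom, pos = pos, ref = "A", var = "G",
                     qual = -1, stringsAsFactors = FALSE)
  gendiv:::build_snv_table(site, geno, names, "gd_genotype")
}

# gd_snp table from per-individual (ref, var, geno, gq) column blocks
snp_table <- function(samples, names, pos = NULL, chrom = NULL, qual = -1) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(chrom)) chrom <- rep("chr1", n)
  site <- data.frame(chrom = chrom, pos = pos, ref = "A", var = "G",
                     qual = qual, stringsAsFactors = FALSE)
  gendiv:::build_snv_table(site, samples, names, "gd_snp")
}

# population covering all individuals of a table
whole_pop <- function(table, name = "all") {
  specify_population(table, individual_names(table), name)
}

# genotype matrix realizing given allele counts: a reference alleles out of
# n (n even), as diploid genotypes
geno_from_counts <- function(a, n) {
  stopifnot(n %% 2 == 0, a <= n)
  g <- integer(n / 2)
  full <- a %/% 2
  g[seq_len(full)] <- 2L
  if (a %% 2 == 1) g[full + 1L] <- 1L
  g
}
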