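#' Pairwise genotype distances between individuals
#'
#' For each pair, the informative sites are those where both genotypes are
#' called and -- in gd_snp mode with `min_depth > 0` -- both individuals have
#' total read depth at least `min_depth`. The distance is the number of
#' genotypic differences divided by the number of informative sites. By
#' default a difference is any site where the called genotypes differ;
#' `allele_sharing = TRUE` instead scores `|g1 - g2| / 2` per site (a
#' heterozygote-homozygote mismatch then counts half).
#'
#' @param table an `snv_table`
#' @param individuals character vector of >= 2 individual names (default all)
#' @param min_depth per-individual minimum read depth for a site to be
#'   informative (0 = off; gd_snp mode only)
#' @param allele_sharing use the half-difference scoring (see above)
#' @return object of class `genotype_dist`: list with symmetric matrix `d`
#'   (zero diagonal, values in [0, 1]) and matrix `informative_sites`
#' @export
pairwise_distances <- function(table, individuals = NULL, min_depth = 0,
                               allele_sharing = FALSE) {
  if (is.null(individuals)) individuals <- table$individuals$name
  if (length(individuals) < 2L) stop("need at least two individuals", call. = FALSE)
  g <- genotype_matrix(table, individuals)
  called <- g != -1L
  if (min_depth > 0) {
    rm_ <- read_matrices(table, individuals)  # errors in gd_genotype mode
    called <- called & rm_$ref >= 0L & rm_$var >= 0L &
      (rm_$ref + rm_$var) >= min_depth
  }
  k <- length(individuals)
  d <- matrix(0, k, k, dimnames = list(individuals, individuals))
  inf <- matrix(0L, k, k, dimnames = list(individuals, individuals))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- called[, i] & called[, j]
      n_inf <- sum(ok)
      if (n_inf == 0L) {
        stop("no informative site for pair ", individuals[i], " / ",
             individuals[j], call. = FALSE)
      }
      diffs <- if (allele_sharing) {
        sum(abs(g[ok, i] - g[ok, j]) / 2)
      } else {
        sum(g[ok, i] != g[ok, j])
      }
      d[i, j] <- d[j, i] <- diffs / n_inf
      inf[i, j] <- inf[j, i] <- n_inf
    }
  }
  structure(list(labels = individuals, d = d, informative_sites = inf),
            class = "genotype_dist")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining on a symmetric distance matrix.
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' clamped to 0 with a warning.
#'
#' @param dm a `genotype_dist` object or a symmetric numeric matrix with
#'   labelled rows (>= 3 taxa)
#' @return an [ape::phylo] unrooted tree
#' @export
neighbor_joining <- function(dm) {
  m <- if (inherits(dm, "genotype_dist")) dm$d else as.matrix(dm)
  if (!isSymmetric(unname(m))) stop("distance matrix must be symmetric", call. = FALSE)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  tree <- ape::nj(stats::as.dist(m))
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Write a tree in Newick format
#' @param tree an [ape::phylo] tree
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a PHYLIP-style distance matrix
#'
#' Square PHYLIP format: a line with the taxon count, then one row per taxon
#' (label followed by its distances).
#'
#' @param dm a `genotype_dist` object or labelled symmetric matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phylip <- function(dm, path) {
  m <- if (inherits(dm, "genotype_dist")) dm$d else as.matrix(dm)
  lines <- c(
    format(nrow(m)),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], format(m[i, ], digits = 10)), collapse = "  ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
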