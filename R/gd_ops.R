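#' Define a population from named individuals
#'
#' A population is a named, non-empty set of individuals resolved against the
#' columns of a host table. Duplicate names are collapsed with a warning;
#' unknown names raise an error listing the table's individuals.
#'
#' @param table an `snv_table`
#' @param names character vector of individual names present in `table`
#' @param pop_name label for the population
#' @return an object of class `population`: list(name, members)
#' @export
specify_population <- function(table, names, pop_name) {
  if (!length(names)) stop("a population must be non-empty", call. = FALSE)
  unknown <- setdiff(names, table$individuals$name)
  if (length(unknown)) {
    stop("unknown individual(s): ", paste(unknown, collapse = ", "),
         "; table has: ", paste(table$individuals$name, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names)) {
    warning("duplicate names collapsed in population '", pop_name, "'")
    names <- unique(names)
  }
  structure(list(name = pop_name, members = names), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %s: %d individual(s): %s\n", x$name,
              length(x$members), paste(x$members, collapse = ", ")))
  invisible(x)
}

check_pop <- function(table, pop) {
  if (!inherits(pop, "population")) stop("not a population object", call. = FALSE)
  missing <- setdiff(pop$members, table$individuals$name)
  if (length(missing)) {
    stop("population '", pop$name, "' has members absent from the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(pop)
}

#' Filter SNVs on coverage, quality and polymorphism
#'
#' A SNV is kept when every member of `pop` passes the active thresholds:
#' total read depth (ref + var reads) within `[min_depth, max_depth]`, site
#' quality at least `min_site_quality` and genotype quality at least
#' `min_geno_quality`. A -1 (absent) read count or quality fails the
#' corresponding active threshold, the conservative reading. With
#' `require_polymorphic`, sites where all called genotypes in `pop` agree
#' (including sites with fewer than two calls) are dropped. Row order is
#' preserved; inactive thresholds (0 / `Inf`) are identity.
#'
#' @param table an `snv_table`
#' @param pop a [specify_population()] object
#' @param min_depth,max_depth per-member total-read-depth bounds (gd_snp only)
#' @param min_site_quality minimum site quality (0 = off)
#' @param min_geno_quality minimum per-member genotype quality (0 = off)
#' @param require_polymorphic drop sites monomorphic within `pop`
#' @return the filtered `snv_table`
#' @export
filter_snvs <- function(table, pop, min_depth = 0, max_depth = Inf,
                        min_site_quality = 0, min_geno_quality = 0,
                        require_polymorphic = FALSE) {
  check_pop(table, pop)
  stopifnot(min_depth >= 0, max_depth >= min_depth,
            min_site_quality >= 0, min_geno_quality >= 0)
  n <- n_snvs(table)
  keep <- rep(TRUE, n)
  if (n == 0L) return(table)
  depth_active <- min_depth > 0 || is.finite(max_depth)
  if (depth_active) {
    if (table$mode != "gd_snp") {
      stop("depth filtering requires read counts (gd_snp mode)", call. = FALSE)
    }
    rm_ <- read_matrices(table, pop$members)
    ok <- rm_$ref >= 0L & rm_$var >= 0L
    depth <- rm_$ref + rm_$var
    pass <- ok & depth >= min_depth & depth <= max_depth
    keep <- keep & rowSums(pass) == length(pop$members)
  }
  if (min_site_quality > 0) {
    keep <- keep & table$data$qual >= min_site_quality
  }
  if (min_geno_quality > 0) {
    if (table$mode != "gd_snp") {
      stop("genotype-quality filtering requires gd_snp mode", call. = FALSE)
    }
    gq <- geno_qual_matrix(table, pop$members)
    keep <- keep & rowSums(gq >= min_geno_quality) == length(pop$members)
  }
  if (require_polymorphic) {
    g <- genotype_matrix(table, pop$members)
    poly <- apply(g, 1L, function(r) {
      r <- r[r != -1L]
      length(unique(r)) >= 2L
    })
    keep <- keep & poly
  }
  subset_rows(table, keep)
}

#' Aggregate a population into pooled allele totals
#'
#' Appends two columns, `<pop>.ref_total` and `<pop>.var_total`. In gd_snp
#' mode these are the summed reference- and variant-read counts over members
#' (-1 entries contribute nothing); in gd_genotype mode they are allele
#' counts from genotypes -- genotype g contributes g reference and 2 - g
#' variant alleles, -1 contributes nothing -- so ref + var = 2 x (called
#' members) at every site.
#'
#' @inheritParams filter_snvs
#' @return the table with the two totals appended
#' @export
aggregate_population <- function(table, pop) {
  check_pop(table, pop)
  if (table$mode == "gd_snp") {
    rm_ <- read_matrices(table, pop$members)
    ref <- rowSums(pmax(rm_$ref, 0L))
    var <- rowSums(pmax(rm_$var, 0L))
  } else {
    g <- genotype_matrix(table, pop$members)
    called <- g != -1L
    ref <- rowSums(g * called)
    var <- rowSums((2L - g) * called)
  }
  table <- add_column(table, paste0(pop$name, ".ref_total"), as.numeric(ref))
  add_column(table, paste0(pop$name, ".var_total"), as.numeric(var))
}

#' Per-individual read-depth distributions
#'
#' Summarizes total read depth (ref + var) per individual across SNVs:
#' mean, median, quartiles and a depth histogram (counts sum to the number of
#' SNVs). Individuals whose median depth falls below half the across-
#' individual median of medians are flagged `low_coverage`.
#'
#' @inheritParams filter_snvs
#' @return data.frame of per-individual summaries with a `histograms`
#'   attribute (a named list of depth count tables)
#' @export
coverage_summary <- function(table, pop) {
  check_pop(table, pop)
  if (table$mode != "gd_snp") {
    stop("coverage summaries require read counts (gd_snp mode)", call. = FALSE)
  }
  rm_ <- read_matrices(table, pop$members)
  depth <- pmax(rm_$ref, 0L) + pmax(rm_$var, 0L)
  stats_one <- function(d) {
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(d), q25 = q[1], median = q[2], q75 = q[3],
      min = min(d), max = max(d))
  }
  s <- t(apply(depth, 2L, stats_one))
  out <- data.frame(individual = pop$members, n_snvs = nrow(depth), s,
                    row.names = NULL, stringsAsFactors = FALSE)
  med_of_med <- stats::median(out$median)
  out$low_coverage <- out$median < med_of_med / 2
  attr(out, "histograms") <- lapply(
    stats::setNames(seq_along(pop$members), pop$members),
    function(j) table(depth[, j]))
  out
}

#' Thin SNVs to a minimum spacing
#'
#' Greedy left-to-right per chromosome: the first SNV is kept, then each
#' subsequent SNV at least `min_spacing` bp from the last kept one.
#'
#' @param table an `snv_table`
#' @param min_spacing minimum distance in bp between consecutive kept SNVs
#' @return the thinned `snv_table`
#' @export
sample_uniform <- function(table, min_spacing) {
  stopifnot(min_spacing > 0)
  d <- table$data
  keep <- logical(nrow(d))
  for (ch in unique(d$chrom)) {
    i <- which(d$chrom == ch)
    last <- -Inf
    for (j in i) {
      if (d$pos[j] - last >= min_spacing) {
        keep[j] <- TRUE
        last <- d$pos[j]
      }
    }
  }
  subset_rows(table, keep)
}
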