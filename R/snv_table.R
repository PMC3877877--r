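#' SNV tables in gd_snp / gd_genotype form
#'
#' An `snv_table` holds one row per single-nucleotide variant (SNV) with five
#' fixed site columns -- chromosome, 1-based position, reference allele,
#' variant allele, site quality (-1 when absent) -- followed by per-individual
#' sample columns. In `gd_snp` mode each individual occupies four columns
#' (reference-read count, variant-read count, genotype, genotype quality); in
#' `gd_genotype` mode a single genotype column. Genotypes count copies of the
#' REFERENCE allele: 2 = homozygous reference, 1 = heterozygous, 0 = homozygous
#' variant, -1 = uncalled. Analyses may append named numeric columns after the
#' sample block (the "chained column" convention), which travel with the table
#' through filtering and subsetting.
#'
#' @name snv_table
#' @keywords internal
NULL

FIXED_COLS <- 5L
GENO_OK <- c(-1L, 0L, 1L, 2L)

new_snv_table <- function(data, individuals, mode, extra = character()) {
  stopifnot(mode %in% c("gd_snp", "gd_genotype"))
  x <- structure(
    list(data = data, individuals = individuals, mode = mode, extra = extra),
    class = "snv_table"
  )
  validate_snv_table(x)
  x
}

validate_snv_table <- function(x) {
  d <- x$data
  ind <- x$individuals
  if (anyDuplicated(ind$name)) {
    stop("individual names must be unique within a table", call. = FALSE)
  }
  ncol_per <- if (x$mode == "gd_snp") 4L else 1L
  expect_fc <- FIXED_COLS + ncol_per * (seq_len(nrow(ind)) - 1L) + 1L
  if (nrow(ind) && !identical(as.integer(ind$first_column), expect_fc)) {
    stop("individual column indices are inconsistent with table mode",
         call. = FALSE)
  }
  if (nrow(d) == 0L) return(invisible(x))
  if (any(d$pos < 1L)) {
    stop("positions must be >= 1 (rows: ",
         paste(utils::head(which(d$pos < 1L), 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  bad_allele <- d$ref == d$var
  if (any(bad_allele)) {
    stop("reference and variant alleles must differ (rows: ",
         paste(utils::head(which(bad_allele), 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  # chrom blocks contiguous, positions strictly increasing within a block
  rle_c <- rle(d$chrom)
  if (anyDuplicated(rle_c$values)) {
    stop("rows of the same chromosome must be contiguous", call. = FALSE)
  }
  dp <- diff(d$pos)
  new_chrom <- cumsum(rle_c$lengths)[-length(rle_c$lengths)]
  dp[new_chrom] <- 1L
  if (any(dp == 0L)) {
    stop("duplicate (chrom, pos) rows are forbidden (rows: ",
         paste(utils::head(which(dp == 0L) + 1L, 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(dp < 0L)) {
    stop("positions must be non-decreasing within a chromosome (rows: ",
         paste(utils::head(which(dp < 0L) + 1L, 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  g <- genotype_matrix(x)
  bad_g <- !(g %in% GENO_OK)
  if (any(bad_g)) {
    rows <- unique(which(matrix(bad_g, nrow = nrow(g)), arr.ind = TRUE)[, 1L])
    stop("genotypes must be in {-1, 0, 1, 2} (rows: ",
         paste(utils::head(sort(rows), 5L), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.snv_table <- function(x, ...) {
  cat(sprintf("<snv_table> %s: %d SNVs, %d individuals, %d extra column(s)\n",
              x$mode, nrow(x$data), nrow(x$individuals), length(x$extra)))
  if (nrow(x$individuals)) {
    cat("individuals:", paste(x$individuals$name, collapse = ", "), "\n")
  }
  if (length(x$extra)) cat("extra:", paste(x$extra, collapse = ", "), "\n")
  invisible(x)
}

#' Number of SNVs in a table
#' @param x an `snv_table`
#' @return integer row count
#' @export
n_snvs <- function(x) nrow(x$data)

#' Individual names in a table
#' @param x an `snv_table`
#' @return character vector of names
#' @export
individual_names <- function(x) x$individuals$name

ind_col <- function(x, name, what = c("geno", "ref", "var", "gq")) {
  what <- match.arg(what)
  i <- match(name, x$individuals$name)
  if (is.na(i)) stop("unknown individual: ", name, call. = FALSE)
  fc <- x$individuals$first_column[i]
  if (x$mode == "gd_genotype") {
    if (what != "geno") stop("gd_genotype tables carry no read counts or genotype qualities",
                             call. = FALSE)
    return(fc)
  }
  fc + switch(what, ref = 0L, var = 1L, geno = 2L, gq = 3L)
}

#' Extract the genotype matrix
#'
#' @param x an `snv_table`
#' @param individuals character vector of individual names (default all)
#' @return integer matrix, one row per SNV, one column per individual;
#'   entries in \{-1, 0, 1, 2\} counting reference-allele copies
#' @export
genotype_matrix <- function(x, individuals = NULL) {
  if (is.null(individuals)) individuals <- x$individuals$name
  cols <- vapply(individuals, function(nm) ind_col(x, nm, "geno"), integer(1))
  m <- as.matrix(x$data[, cols, drop = FALSE])
  storage.mode(m) <- "integer"
  colnames(m) <- individuals
  m
}

#' Extract read-count matrices (gd_snp mode only)
#'
#' @inheritParams genotype_matrix
#' @return list with integer matrices `ref` and `var` (-1 = absent)
#' @export
read_matrices <- function(x, individuals = NULL) {
  if (x$mode != "gd_snp") {
    stop("read counts are only present in gd_snp tables", call. = FALSE)
  }
  if (is.null(individuals)) individuals <- x$individuals$name
  grab <- function(what) {
    cols <- vapply(individuals, function(nm) ind_col(x, nm, what), integer(1))
    m <- as.matrix(x$data[, cols, drop = FALSE])
    storage.mode(m) <- "integer"
    colnames(m) <- individuals
    m
  }
  list(ref = grab("ref"), var = grab("var"))
}

geno_qual_matrix <- function(x, individuals = NULL) {
  if (x$mode != "gd_snp") {
    stop("genotype qualities are only present in gd_snp tables", call. = FALSE)
  }
  if (is.null(individuals)) individuals <- x$individuals$name
  cols <- vapply(individuals, function(nm) ind_col(x, nm, "gq"), integer(1))
  m <- as.matrix(x$data[, cols, drop = FALSE])
  colnames(m) <- individuals
  m
}

#' Append a named numeric column to a table
#'
#' Analyses chain by appending score columns (per-SNP F_ST, homozygosity, ...)
#' after the sample block.
#'
#' @param x an `snv_table`
#' @param name column label
#' @param values numeric vector, one value per SNV (NA = unscored)
#' @return the table with the column appended
#' @export
add_column <- function(x, name, values) {
  stopifnot(length(values) == nrow(x$data))
  if (name %in% names(x$data)) stop("column already present: ", name, call. = FALSE)
  x$data[[name]] <- values
  x$extra <- c(x$extra, name)
  x
}

#' Row-subset a table, keeping all metadata
#' @param x an `snv_table`
#' @param i logical or integer row index (original order is preserved)
#' @return the subsetted `snv_table`
#' @export
subset_rows <- function(x, i) {
  x$data <- x$data[i, , drop = FALSE]
  rownames(x$data) <- NULL
  x
}

sample_col_names <- function(ind_names, mode) {
  if (mode == "gd_snp") {
    as.vector(t(outer(ind_names, c("ref_reads", "var_reads", "geno", "gq"),
                      paste, sep = ".")))
  } else {
    ind_names
  }
}

build_snv_table <- function(site, samples, ind_names, mode, extra_df = NULL) {
  # site: data.frame(chrom, pos, ref, var, qual); samples: numeric matrix
  d <- cbind(site, as.data.frame(samples))
  names(d) <- c("chrom", "pos", "ref", "var", "qual",
                sample_col_names(ind_names, mode))
  extra <- character()
  if (!is.null(extra_df) && ncol(extra_df)) {
    d <- cbind(d, extra_df)
    extra <- names(extra_df)
  }
  per <- if (mode == "gd_snp") 4L else 1L
  individuals <- data.frame(
    name = ind_names,
    first_column = FIXED_COLS + per * (seq_along(ind_names) - 1L) + 1L,
    alias = ind_names,
    stringsAsFactors = FALSE
  )
  new_snv_table(d, individuals, mode, extra)
}
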