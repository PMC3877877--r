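#' Read a gd_snp table
#'
#' Tab-delimited, one row per SNV. Header lines begin with `#`:
#' `#format gd_snp` on the first line, then one `#individual <name>
#' <first_column>` line per individual (first_column is the 1-based index of
#' the individual's first data column; individuals occupy four consecutive
#' columns in gd_snp, one in gd_genotype), and optionally `#column <name>
#' <index>` lines declaring extra score columns appended after the sample
#' block. Data rows carry chrom, pos, ref allele, var allele, site quality,
#' then the sample columns.
#'
#' @param path file path
#' @return an `snv_table` in gd_snp mode
#' @export
read_gd_snp <- function(path) read_gd(path, "gd_snp")

#' Read a gd_genotype table
#'
#' As [read_gd_snp()] but with a single genotype column per individual; read
#' counts and genotype qualities are absent (uniformly -1).
#'
#' @param path file path
#' @return an `snv_table` in gd_genotype mode
#' @export
read_gd_genotype <- function(path) read_gd(path, "gd_genotype")

read_gd <- function(path, mode) {
  lines <- readLines(path)
  is_head <- startsWith(lines, "#")
  if (!length(lines) || !is_head[1L]) {
    stop("missing header: gd files must start with '#format ", mode, "'",
         call. = FALSE)
  }
  n_head <- match(FALSE, is_head, nomatch = length(lines) + 1L) - 1L
  head_lines <- lines[seq_len(n_head)]
  fmt <- sub("^#format\\s+", "", grep("^#format\\s", head_lines, value = TRUE))
  if (length(fmt) != 1L) {
    stop("missing header: expected one '#format' line", call. = FALSE)
  }
  if (fmt != mode) {
    stop("format mismatch: file declares '", fmt, "', expected '", mode, "'",
         call. = FALSE)
  }
  ind_lines <- grep("^#individual\\s", head_lines, value = TRUE)
  if (!length(ind_lines)) {
    stop("missing header: no '#individual' lines declare the samples",
         call. = FALSE)
  }
  parts <- strsplit(sub("^#individual\\s+", "", ind_lines), "\\s+")
  ind_names <- vapply(parts, `[`, character(1), 1L)
  first_col <- as.integer(vapply(parts, `[`, character(1), 2L))
  o <- order(first_col)
  ind_names <- ind_names[o]
  first_col <- first_col[o]
  col_lines <- grep("^#column\\s", head_lines, value = TRUE)
  extra_names <- if (length(col_lines)) {
    cp <- strsplit(sub("^#column\\s+", "", col_lines), "\\s+")
    en <- vapply(cp, `[`, character(1), 1L)
    en[order(as.integer(vapply(cp, `[`, character(1), 2L)))]
  } else character()

  per <- if (mode == "gd_snp") 4L else 1L
  n_ind <- length(ind_names)
  want_cols <- FIXED_COLS + per * n_ind + length(extra_names)

  body <- lines[-seq_len(n_head)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    site <- data.frame(chrom = character(), pos = integer(), ref = character(),
                       var = character(), qual = numeric(),
                       stringsAsFactors = FALSE)
    samples <- matrix(numeric(), 0L, per * n_ind)
    extra_df <- if (length(extra_names)) {
      stats::setNames(as.data.frame(matrix(numeric(), 0L, length(extra_names))),
                      extra_names)
    } else NULL
    return(build_snv_table(site, samples, ind_names, mode, extra_df))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != want_cols)) {
    bad <- which(nf != want_cols)[1L]
    stop("malformed row at line ", n_head + bad, ": expected ", want_cols,
         " tab-delimited fields, found ", nf[bad], call. = FALSE)
  }
  m <- matrix(unlist(fields), nrow = length(body), byrow = TRUE)
  site <- data.frame(
    chrom = m[, 1L],
    pos = as.integer(m[, 2L]),
    ref = m[, 3L],
    var = m[, 4L],
    qual = as.numeric(m[, 5L]),
    stringsAsFactors = FALSE
  )
  sm <- m[, FIXED_COLS + seq_len(per * n_ind), drop = FALSE]
  samples <- matrix(as.numeric(sm), nrow = nrow(m))
  extra_df <- NULL
  if (length(extra_names)) {
    em <- m[, FIXED_COLS + per * n_ind + seq_along(extra_names), drop = FALSE]
    extra_df <- stats::setNames(
      as.data.frame(matrix(as.numeric(em), nrow = nrow(m))), extra_names)
  }
  if (anyNA(site$pos)) {
    stop("malformed row at line ",
         n_head + which(is.na(site$pos))[1L], ": position is not an integer",
         call. = FALSE)
  }
  # report genotype violations with file line numbers before generic validation
  gidx <- if (mode == "gd_snp") seq(3L, per * n_ind, by = 4L) else seq_len(n_ind)
  g <- samples[, gidx, drop = FALSE]
  bad <- which(!(g %in% GENO_OK) | is.na(g))
  if (length(bad)) {
    row <- ((bad[1L] - 1L) %% nrow(g)) + 1L
    stop("genotype outside {-1, 0, 1, 2} at line ", n_head + row, call. = FALSE)
  }
  build_snv_table(site, samples, ind_names, mode, extra_df)
}

#' Write a gd_snp / gd_genotype table
#'
#' Emits the canonical header dialect understood by [read_gd_snp()] /
#' [read_gd_genotype()]; `write(read(f))` is byte-identical to `f` for files
#' produced by this writer.
#'
#' @param x an `snv_table`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gd_snp <- function(x, path) {
  if (x$mode != "gd_snp") stop("table is not in gd_snp mode", call. = FALSE)
  write_gd(x, path)
}

#' @rdname write_gd_snp
#' @export
write_gd_genotype <- function(x, path) {
  if (x$mode != "gd_genotype") stop("table is not in gd_genotype mode", call. = FALSE)
  write_gd(x, path)
}

write_gd <- function(x, path) {
  head <- c(
    paste("#format", x$mode),
    sprintf("#individual %s %d", x$individuals$name, x$individuals$first_column)
  )
  per <- if (x$mode == "gd_snp") 4L else 1L
  base_n <- FIXED_COLS + per * nrow(x$individuals)
  if (length(x$extra)) {
    head <- c(head, sprintf("#column %s %d", x$extra,
                            base_n + seq_along(x$extra)))
  }
  num <- function(v) {
    out <- vapply(v, function(z) format(z, scientific = FALSE, trim = TRUE),
                  character(1))
    out
  }
  d <- x$data
  cols <- c(list(d$chrom, num(d$pos), d$ref, d$var, num(d$qual)),
            lapply(d[, -(1:FIXED_COLS), drop = FALSE], num))
  body <- if (nrow(d)) do.call(paste, c(cols, sep = "\t")) else character()
  writeLines(c(head, body), path)
  invisible(path)
}

#' Convert a VCF to a gd_snp table
#'
#' Uses the per-sample GT (required), AD and GQ (optional, -1 when absent)
#' FORMAT fields. GT `0/0` maps to genotype 2, `0/1` / `1/0` to 1, `1/1` to 0
#' and `./.` to -1 (genotypes count reference-allele copies). The first two
#' AD values become the reference- and variant-read counts. Multi-allelic
#' rows are skipped; their count is attached as attribute `n_multiallelic`
#' and reported via a message.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file
#' @return an `snv_table` in gd_snp mode
#' @export
convert_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt_field <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt_field, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1)))) {
    stop("unsupported input: every VCF row must carry GT in FORMAT",
         call. = FALSE)
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi) {
    message("skipped ", n_multi, " multi-allelic site(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  gq <- tryCatch(vcfR::extract.gt(v, element = "GQ"), error = function(e) NULL)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (!is.null(ad)) ad <- ad[keep, , drop = FALSE]
  if (!is.null(gq)) gq <- gq[keep, , drop = FALSE]
  n <- nrow(fix)
  ind_names <- colnames(gt)
  k <- length(ind_names)

  geno_map <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(-1L, length(g))
    out[g %in% "0/0"] <- 2L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 0L
    out
  }
  samples <- matrix(-1, nrow = n, ncol = 4L * k)
  for (j in seq_len(k)) {
    samples[, 4L * j - 1L] <- geno_map(gt[, j])
    if (!is.null(ad)) {
      parts <- strsplit(ifelse(is.na(ad[, j]), ".", ad[, j]), ",", fixed = TRUE)
      r <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
      a <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 2L) p[2L] else NA_character_, character(1))))
      samples[, 4L * j - 3L] <- ifelse(is.na(r), -1L, r)
      samples[, 4L * j - 2L] <- ifelse(is.na(a), -1L, a)
    }
    if (!is.null(gq)) {
      q <- suppressWarnings(as.numeric(gq[, j]))
      samples[, 4L * j] <- ifelse(is.na(q), -1, q)
    }
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  site <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    var = fix[, "ALT"],
    qual = ifelse(is.na(qual), -1, qual),
    stringsAsFactors = FALSE
  )
  out <- build_snv_table(site, samples, ind_names, "gd_snp")
  attr(out, "n_multiallelic") <- n_multi
  out
}
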