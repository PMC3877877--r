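test_that("gd_snp files parse, validate and round-trip", {
  f <- withr::local_tempfile()
  writeLines(c(
    "#format gd_snp",
    "#individual s1 6",
    "#individual s2 10",
    paste("chr1", 100, "A", "G", 40, 10, 0, 2, 50, 3, 7, 1, 30, sep = "\t"),
    paste("chr1", 200, "C", "T", -1, 0, 12, 0, 45, 6, 6, 1, 28, sep = "\t")
  ), f)
  tab <- read_gd_snp(f)
  expect_equal(n_snvs(tab), 2L)
  expect_equal(individual_names(tab), c("s1", "s2"))
  expect_equal(unname(genotype_matrix(tab)[, "s1"]), c(2L, 0L))
  rm_ <- read_matrices(tab, "s2")
  expect_equal(unname(rm_$ref[, 1]), c(3L, 6L))

  # writer output re-reads byte-identically
  f2 <- withr::local_tempfile()
  write_gd_snp(tab, f2)
  f3 <- withr::local_tempfile()
  write_gd_snp(read_gd_snp(f2), f3)
  expect_identical(readLines(f2), readLines(f3))

  # malformed content is reported with its line number
  bad <- withr::local_tempfile()
  writeLines(c(
    "#format gd_snp", "#individual s1 6",
    paste("chr1", 100, "A", "G", 40, 10, 0, 3, 50, sep = "\t")
  ), bad)
  expect_error(read_gd_snp(bad), "genotype.*line 3")

  nohead <- withr::local_tempfile()
  writeLines(paste("chr1", 100, "A", "G", 40, 10, 0, 2, 50, sep = "\t"), nohead)
  expect_error(read_gd_snp(nohead), "header")
})

test_that("gd_genotype files parse with absent read data, including empty bodies", {
  f <- withr::local_tempfile()
  writeLines(c(
    "#format gd_genotype",
    "#individual s1 6",
    paste("chr1", c(10, 20, 30), "A", "G", -1, c(2, 1, -1), sep = "\t")
  ), f)
  tab <- read_gd_genotype(f)
  expect_equal(n_snvs(tab), 3L)
  expect_error(read_matrices(tab), "gd_snp")

  empty <- withr::local_tempfile()
  writeLines(c("#format gd_genotype", "#individual s1 6"), empty)
  tab0 <- read_gd_genotype(empty)
  expect_equal(n_snvs(tab0), 0L)

  # aggregation from genotypes alone still works (pooled-allele counting)
  agg <- aggregate_population(tab, whole_pop(tab))
  expect_equal(agg$data$all.ref_total, c(2, 1, 0))
  expect_equal(agg$data$all.var_total, c(0, 1, 0))
})

test_that("tables with duplicate or unsorted positions are rejected", {
  expect_error(geno_table(matrix(c(2L, 1L), 2, 1), pos = c(100L, 100L)),
               "duplicate")
  expect_error(geno_table(matrix(c(2L, 1L), 2, 1), pos = c(200L, 100L)),
               "non-decreasing")
})

test_that("VCF conversion maps GT/AD/GQ and skips multi-allelic rows", {
  f <- withr::local_tempfile()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNA1\tNA2",
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD:GQ\t0/1:7,5:40\t0/0:9,0:60",
    "chr1\t200\t.\tC\tT,G\t50\tPASS\t.\tGT:AD:GQ\t1/1:0,8:30\t0/1:4,4:50",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t1/1"
  ), f)
  tab <- suppressMessages(convert_vcf(f))
  expect_equal(n_snvs(tab), 2L)           # tri-allelic row dropped
  expect_equal(attr(tab, "n_multiallelic"), 1L)
  expect_equal(unname(genotype_matrix(tab)[, "NA1"]), c(1L, -1L))
  expect_equal(unname(genotype_matrix(tab)[, "NA2"]), c(2L, 0L))
  rm_ <- read_matrices(tab, "NA1")
  expect_equal(rm_$ref[1, 1][[1]], 7L)
  expect_equal(rm_$var[1, 1][[1]], 5L)
  expect_equal(unname(gendiv:::geno_qual_matrix(tab, "NA1")[, 1]), c(40, -1))
  expect_equal(rm_$ref[2, 1][[1]], -1L)   # absent AD -> placeholder
  expect_equal(tab$data$qual, c(50, -1))
})

test_that("populations resolve names, reject unknowns and deduplicate", {
  tab <- geno_table(matrix(2L, 2, 4), names = paste0("North", 1:4))
  pop <- specify_population(tab, paste0("North", 1:4), "North")
  expect_equal(length(pop$members), 4L)
  expect_error(specify_population(tab, "South1", "S"), "unknown.*South1")
  expect_error(specify_population(tab, character(), "E"), "non-empty")
  expect_warning(p2 <- specify_population(tab, c("North1", "North1"), "N"),
                 "duplicate")
  expect_equal(p2$members, "North1")
})

test_that("depth/quality/polymorphism filters keep the stated rows in order", {
  # one individual with per-SNV depths 10, 3, 12
  samples <- cbind(c(7L, 2L, 6L), c(3L, 1L, 6L), c(1L, 1L, 1L), c(50, 50, 50))
  tab <- snp_table(samples, "s1")
  pop <- whole_pop(tab)
  kept <- filter_snvs(tab, pop, min_depth = 8)
  expect_equal(n_snvs(kept), 2L)
  expect_equal(kept$data$pos, c(100L, 300L))  # original order

  # -1 read count fails an active depth filter
  s2 <- cbind(c(-1L, 7L), c(0L, 3L), c(2L, 1L), c(50, 50))
  t2 <- snp_table(s2, "s1")
  expect_equal(n_snvs(filter_snvs(t2, whole_pop(t2), min_depth = 1)), 1L)

  # monomorphic sites drop under require_polymorphic
  g <- rbind(c(2L, 2L, 2L), c(2L, 1L, 0L), c(-1L, 1L, 1L))
  t3 <- geno_table(g)
  kept3 <- filter_snvs(t3, whole_pop(t3), require_polymorphic = TRUE)
  expect_equal(kept3$data$pos, 200L)

  # no active thresholds: identity
  expect_equal(filter_snvs(tab, pop)$data, tab$data)
})

test_that("aggregation totals follow the genotype-counting rule", {
  g <- matrix(c(2L, 1L, 0L, -1L), 1, 4)
  tab <- geno_table(g)
  agg <- aggregate_population(tab, whole_pop(tab))
  expect_equal(agg$data$all.ref_total, 3)
  expect_equal(agg$data$all.var_total, 3)

  # gd_snp mode sums reads
  s <- cbind(c(12L), c(0L), c(2L), c(50))
  s <- cbind(s, c(18L), c(0L), c(2L), c(50))
  t2 <- snp_table(matrix(s, 1), c("a", "b"))
  agg2 <- aggregate_population(t2, whole_pop(t2))
  expect_equal(agg2$data$all.ref_total, 30)
  expect_equal(agg2$data$all.var_total, 0)

  # empty site
  t3 <- geno_table(matrix(-1L, 1, 3))
  agg3 <- aggregate_population(t3, whole_pop(t3))
  expect_equal(agg3$data$all.ref_total, 0)
  expect_equal(agg3$data$all.var_total, 0)

  # invariant: ref + var = 2 x called members in genotype mode
  set.seed(42)
  g4 <- matrix(sample(c(-1L, 0L, 1L, 2L), 200, replace = TRUE), 50, 4)
  t4 <- geno_table(g4)
  a4 <- aggregate_population(t4, whole_pop(t4))
  called <- rowSums(g4 != -1L)
  expect_equal(a4$data$all.ref_total + a4$data$all.var_total, 2 * called)
})

test_that("coverage summaries report depth distributions and flag outliers", {
  s <- cbind(c(2L, 2L, 4L), c(2L, 2L, 4L), c(2L, 2L, 2L), c(50, 50, 50),
             c(0L, 0L, 0L), c(0L, 0L, 0L), c(2L, 2L, 2L), c(50, 50, 50))
  tab <- snp_table(s, c("good", "empty"))
  cs <- coverage_summary(tab, whole_pop(tab))
  expect_equal(cs$mean[cs$individual == "good"], 16 / 3)
  expect_equal(cs$median[cs$individual == "good"], 4)
  expect_true(cs$low_coverage[cs$individual == "empty"])
  expect_false(cs$low_coverage[cs$individual == "good"])
  h <- attr(cs, "histograms")
  expect_equal(sum(h$good), n_snvs(tab))
  expect_equal(sum(h$empty), n_snvs(tab))
})

test_that("uniform sampling keeps the greedy left-to-right SNV set", {
  tab <- geno_table(matrix(2L, 4, 1), pos = c(1L, 50000L, 120000L, 260000L))
  kept <- sample_uniform(tab, 100000)
  expect_equal(kept$data$pos, c(1L, 120000L, 260000L))
  expect_equal(n_snvs(sample_uniform(tab, 1)), 4L)
  one <- geno_table(matrix(2L, 1, 1))
  expect_equal(n_snvs(sample_uniform(one, 1e9)), 1L)

  # spacing invariant on random tables
  set.seed(7)
  pos <- sort(sample.int(1e6, 300))
  t2 <- geno_table(matrix(2L, 300, 1), pos = pos)
  for (sp in c(500, 5000, 50000)) {
    out <- sample_uniform(t2, sp)
    expect_true(all(diff(out$data$pos) >= sp))
  }
})

test_that("synth-written fixtures round-trip field-identically in both formats", {
  sim <- simulate_populations(n_pops = 2, n_per_pop = 3, n_snvs = 40,
                              F = 0.2, seed = 5)
  f <- withr::local_tempfile()
  write_gd_genotype(sim$table, f)
  back <- read_gd_genotype(f)
  expect_equal(back$data, sim$table$data)
  expect_equal(back$individuals, sim$table$individuals)

  sim2 <- simulate_populations(n_pops = 2, n_per_pop = 2, n_snvs = 30,
                               F = 0.1, depth_mean = 12, seed = 6)
  tab2 <- aggregate_population(sim2$table, sim2$pops[[1]])
  f2 <- withr::local_tempfile()
  write_gd_snp(tab2, f2)
  back2 <- read_gd_snp(f2)
  expect_equal(back2$data, tab2$data)
  expect_equal(back2$extra, tab2$extra)   # chained columns survive I/O
})
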