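# Weir & Cockerham (1984) a/b/c components transcribed for general r
# populations, evaluated at r = 2 (loop-and-sum route, distinct from the
# package's vectorized two-population code path)
wc_oracle <- function(nind, p, h) {
  r <- length(nind)
  nbar <- mean(nind)
  nc <- (r * nbar - sum(nind^2) / (r * nbar)) / (r - 1)
  pbar <- sum(nind * p) / (r * nbar)
  s2 <- sum(nind * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(nind * h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
    (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

test_that("allele frequencies and homozygosity follow their closed forms", {
  expect_equal(allele_frequency(8, 10), 0.8)
  expect_equal(allele_frequency(0, 10), 0)
  expect_equal(allele_frequency(10, 10), 1)
  expect_error(allele_frequency(0, 0), "undefined")

  expect_equal(homozygosity_score(30, 0), 1)
  expect_equal(homozygosity_score(10, 10), 0.5)
  expect_equal(homozygosity_score(3, 1), 0.625)
  expect_error(homozygosity_score(0, 0), "undefined")

  # symmetric, minimized at r = v, equals 1 iff one count is 0
  grid <- expand.grid(r = 0:12, v = 0:12)
  grid <- grid[grid$r + grid$v > 0, ]
  h <- homozygosity_score(grid$r, grid$v)
  expect_equal(h, homozygosity_score(grid$v, grid$r))
  expect_true(all(h >= 0.5 & h <= 1))
  expect_equal(h == 1, grid$r == 0 | grid$v == 0)
  expect_equal(h == 0.5, grid$r == grid$v)
})

test_that("pi matches brute-force mean pairwise differences; theta the Watterson form", {
  # one SNV, alleles {R,R,V,V}
  tab <- geno_table(matrix(c(2L, 0L), 1, 2))
  nd <- nucleotide_diversity(tab, whole_pop(tab))
  expect_equal(nd$pi, 2 / 3)
  expect_equal(nd$pi, pi_site_oracle(2, 4))
  expect_equal(nd$theta, 1 / (1 + 1 / 2 + 1 / 3))

  # monomorphic table
  mono <- geno_table(matrix(2L, 5, 3))
  nd0 <- nucleotide_diversity(mono, whole_pop(mono))
  expect_equal(nd0$pi, 0)
  expect_equal(nd0$theta, 0)

  # closed form equals enumeration on random fixtures (n <= 20 alleles),
  # with missing genotypes thinning n per site
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    g <- matrix(sample(c(-1L, 0L, 1L, 2L), 30 * k, replace = TRUE,
                       prob = c(0.1, 0.3, 0.3, 0.3)), 30, k)
    tab <- geno_table(g)
    nd <- nucleotide_diversity(tab, whole_pop(tab))
    expected <- sum(apply(g, 1, function(r) {
      r <- r[r != -1L]
      n <- 2L * length(r)
      if (n < 2L) return(0)
      pi_site_oracle(sum(r), n)
    }))
    expect_equal(nd$pi, expected)
  }

  # per-bp normalization
  ndL <- nucleotide_diversity(tab, whole_pop(tab), L = 1000)
  expect_equal(ndL$pi_per_bp, ndL$pi / 1000)

  allmiss <- geno_table(matrix(-1L, 3, 2))
  expect_error(nucleotide_diversity(allmiss, whole_pop(allmiss)), "called")
})

test_that("Wright F_ST gives 0.36 at p = (0.8, 0.2) and stays in [0, 1]", {
  g1 <- geno_from_counts(8, 10)   # p1 = 0.8
  g2 <- geno_from_counts(2, 10)   # p2 = 0.2
  tab <- geno_table(matrix(c(g1, g2), 1, 10),
                    names = c(paste0("a", 1:5), paste0("b", 1:5)))
  p1 <- specify_population(tab, paste0("a", 1:5), "A")
  p2 <- specify_population(tab, paste0("b", 1:5), "B")
  expect_equal(overall_fst(tab, p1, p2, "wright"), 0.36)

  scored <- per_snp_fst(tab, p1, p2, "wright")
  expect_equal(scored$data$fst.A.B, 0.36)

  # in [0,1] across random tables, 0 when mean frequency is degenerate
  set.seed(13)
  g <- matrix(sample(c(-1L, 0L, 1L, 2L), 100 * 8, replace = TRUE), 100, 8)
  t2 <- geno_table(g)
  q1 <- specify_population(t2, paste0("ind", 1:4), "P1")
  q2 <- specify_population(t2, paste0("ind", 5:8), "P2")
  v <- per_snp_fst(t2, q1, q2, "wright")$data$fst.P1.P2
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))

  degen <- geno_table(matrix(2L, 1, 4))
  d1 <- specify_population(degen, c("ind1", "ind2"), "D1")
  d2 <- specify_population(degen, c("ind3", "ind4"), "D2")
  expect_equal(per_snp_fst(degen, d1, d2, "wright")$data$fst.D1.D2, 0)
})

test_that("Reich estimator matches its scalar oracle over random count configurations", {
  set.seed(17)
  for (rep in 1:25) {
    k1 <- sample(2:8, 1)
    k2 <- sample(2:8, 1)
    n <- 40
    g <- cbind(
      matrix(sample(0:2, n * k1, replace = TRUE), n, k1),
      matrix(sample(0:2, n * k2, replace = TRUE), n, k2)
    )
    tab <- geno_table(g)
    p1 <- specify_population(tab, paste0("ind", 1:k1), "P1")
    p2 <- specify_population(tab, paste0("ind", k1 + 1:k2), "P2")
    a1 <- rowSums(g[, 1:k1, drop = FALSE])
    a2 <- rowSums(g[, k1 + 1:k2, drop = FALSE])
    oN <- oD <- numeric(n)
    oF <- numeric(n)
    for (i in 1:n) {
      o <- reich_oracle(a1[i], 2 * k1, a2[i], 2 * k2)
      oN[i] <- o$N; oD[i] <- o$D
      oF[i] <- o$N / o$D
    }
    got <- per_snp_fst(tab, p1, p2, "reich")$data$fst.P1.P2
    expect_equal(got, oF)
    expect_equal(overall_fst(tab, p1, p2, "reich"), sum(oN) / sum(oD))
    expect_true(all(got[!is.na(got)] <= 1 + 1e-12))
  }

  # the worked configuration a1=8/n1=10 vs a2=2/n2=10
  o <- reich_oracle(8, 10, 2, 10)
  expect_equal(o$N, 0.36 - 2 * (16 / 90) / 10)
  expect_equal(o$D, 0.68)
  g <- matrix(c(geno_from_counts(8, 10), geno_from_counts(2, 10)), 1, 10)
  tab <- geno_table(g)
  p1 <- specify_population(tab, paste0("ind", 1:5), "P1")
  p2 <- specify_population(tab, paste0("ind", 6:10), "P2")
  expect_equal(per_snp_fst(tab, p1, p2, "reich")$data$fst.P1.P2, o$N / o$D)
})

test_that("every estimator returns 1 when populations are fixed for opposite alleles", {
  g <- matrix(c(rep(2L, 4), rep(0L, 4)), 1, 8)
  tab <- geno_table(g)
  p1 <- specify_population(tab, paste0("ind", 1:4), "P1")
  p2 <- specify_population(tab, paste0("ind", 5:8), "P2")
  for (est in c("wright", "reich", "weir_cockerham")) {
    expect_equal(overall_fst(tab, p1, p2, est), 1)
  }
})

test_that("Weir-Cockerham agrees with the general-r component transcription", {
  set.seed(19)
  for (rep in 1:10) {
    g <- matrix(sample(c(-1L, 0L, 1L, 2L), 50 * 10, replace = TRUE,
                       prob = c(0.1, 0.3, 0.3, 0.3)), 50, 10)
    tab <- geno_table(g)
    p1 <- specify_population(tab, paste0("ind", 1:5), "P1")
    p2 <- specify_population(tab, paste0("ind", 6:10), "P2")
    got <- per_snp_fst(tab, p1, p2, "weir_cockerham")$data$fst.P1.P2
    for (i in seq_len(nrow(g))) {
      g1 <- g[i, 1:5]; g1 <- g1[g1 != -1L]
      g2 <- g[i, 6:10]; g2 <- g2[g2 != -1L]
      if (length(g1) < 1 || length(g2) < 1 || length(g1) + length(g2) <= 2) {
        expect_true(is.na(got[i]))
      } else {
        o <- wc_oracle(c(length(g1), length(g2)),
                       c(mean(g1) / 2, mean(g2) / 2),
                       c(mean(g1 == 1L), mean(g2 == 1L)))
        expect_equal(got[i], o)
      }
    }
  }
})

test_that("overall F_ST is a ratio of sums, not a mean of ratios", {
  one <- geno_table(matrix(c(2L, 2L, 1L, 0L, 0L, 1L), 1, 6))
  p1 <- specify_population(one, paste0("ind", 1:3), "P1")
  p2 <- specify_population(one, paste0("ind", 4:6), "P2")
  per <- per_snp_fst(one, p1, p2, "reich")$data$fst.P1.P2
  expect_equal(overall_fst(one, p1, p2, "reich"), per)

  # identical counts at two SNVs: overall equals the shared per-SNP value
  two <- geno_table(matrix(rep(c(2L, 2L, 1L, 0L, 0L, 1L), each = 2), 2, 6))
  q1 <- specify_population(two, paste0("ind", 1:3), "P1")
  q2 <- specify_population(two, paste0("ind", 4:6), "P2")
  expect_equal(overall_fst(two, q1, q2, "reich"), per)

  # on a larger table ratio-of-sums differs from the mean of per-SNP values
  set.seed(23)
  g <- matrix(sample(0:2, 100 * 6, replace = TRUE), 100, 6)
  t3 <- geno_table(g)
  r1 <- specify_population(t3, paste0("ind", 1:3), "P1")
  r2 <- specify_population(t3, paste0("ind", 4:6), "P2")
  per3 <- per_snp_fst(t3, r1, r2, "reich")$data$fst.P1.P2
  ov <- overall_fst(t3, r1, r2, "reich")
  expect_false(isTRUE(all.equal(ov, mean(per3, na.rm = TRUE))))
})

test_that("LSBL is the three-point branch length and is additive", {
  expect_equal(lsbl(0.3, 0.2, 0.1), 0.2)
  expect_equal(lsbl(0.4, 0.4, 0.4), 0.2)
  expect_equal(lsbl(0, 0, 0.4), -0.2)   # negative branches reported as-is

  set.seed(29)
  f_ab <- runif(50); f_ac <- runif(50); f_bc <- runif(50)
  expect_equal(lsbl(f_ab, f_ac, f_bc) + lsbl(f_ab, f_bc, f_ac), f_ab)
})
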