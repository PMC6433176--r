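test_that("make_windows tiles chromosomes with a short terminal window", {
  w <- make_windows(c(chr1 = 250000), 100000)
  expect_equal(nrow(w), 3L)
  expect_equal(w$end - w$start, c(100000, 100000, 50000))
  expect_equal(nrow(make_windows(c(chr1 = 100000), 100000)), 1L)
  expect_equal(nrow(make_windows(stats::setNames(rep(1e6, 7),
                                                 paste0("chr", 1:7)), 1e5)),
               70L)
  expect_warning(make_windows(c(chr1 = 0, chr2 = 1e5), 1e5), "zero-length")
  expect_error(make_windows(c(chr1 = 1e5), 0), "> 0")
})

test_that("pi matches the worked example and the brute-force oracle", {
  # 2 diploid samples, one site with counts (2,2), L = 100
  gm <- toy_gm(rbind(c(1L, 1L)), chrom_len = 100L)
  ac <- allele_counts(gm)
  expect_equal(nucleotide_diversity(ac, 100), 4 / 6 / 100, tolerance = 1e-12)
  # monomorphic window -> 0
  expect_equal(nucleotide_diversity(allele_counts(toy_gm(rbind(c(0L, 0L)))),
                                    100), 0)
  # all-missing -> 0 contribution
  expect_equal(nucleotide_diversity(allele_counts(toy_gm(rbind(c(NA, NA)))),
                                    100), 0)
  expect_error(nucleotide_diversity(ac, 0), "> 0")
  # oracle equivalence on random matrices (<= 8 x 50), incl. missing data
  set.seed(42)
  for (i in 1:5) {
    gm <- random_gm(50, 8, miss = c(0, 0.1)[i %% 2 + 1])
    L <- 1e4
    expect_equal(nucleotide_diversity(allele_counts(gm), L),
                 oracle_pi(gm, gm$samples, L), tolerance = 1e-12)
    expect_equal(khat_from_counts(allele_counts(gm)),
                 oracle_khat(gm, gm$samples), tolerance = 1e-12)
  }
})

test_that("tajimas_d matches an independent Tajima (1989) evaluation", {
  # n = 4 alleles, two sites with derived counts {1, 2}
  gm <- toy_gm(rbind(c(1L, 0L), c(1L, 1L)))
  d <- tajimas_d(allele_counts(gm))
  expect_equal(d, oracle_tajima(c(1, 2), 4), tolerance = 1e-9)
  expect_equal(round(d, 3), 0.592)
  # S = 0 -> undefined sentinel, never 0
  expect_true(is.na(tajimas_d(allele_counts(toy_gm(rbind(c(0L, 0L)))))))
  # larger random check with complete data
  set.seed(7)
  g <- matrix(sample(0:2, 30 * 6, replace = TRUE), 30, 6)
  gm2 <- toy_gm(g)
  ac <- allele_counts(gm2)
  poly <- ac[, "alt"] > 0 & ac[, "ref"] > 0
  expect_equal(tajimas_d(ac),
               oracle_tajima(ac[poly, "alt"], 12), tolerance = 1e-9)
})

test_that("Weir-Cockerham FST matches independent variance components", {
  # single site, haploid-style counts: pop1 (6,2), pop2 (1,7)
  c1 <- cbind(ref = 6, alt = 2, total = 8)
  c2 <- cbind(ref = 1, alt = 7, total = 8)
  f <- wc_fst(c1, c2)
  o <- oracle_wc(8, 2 / 8, 8, 7 / 8)
  expect_equal(f$weighted, o["a"] / sum(o), ignore_attr = TRUE,
               tolerance = 1e-12)
  # diploid with heterozygotes on random fixtures
  set.seed(11)
  for (i in 1:5) {
    gm <- random_gm(40, 10)
    p1 <- gm$samples[1:5]; p2 <- gm$samples[6:10]
    a1 <- allele_counts(gm, p1); a2 <- allele_counts(gm, p2)
    h1 <- het_counts(gm, p1); h2 <- het_counts(gm, p2)
    comp <- wc_components(a1, a2, h1, h2)
    for (s in sample(40, 5)) {
      o <- oracle_wc(h1[s, "n_called"], a1[s, "alt"] / a1[s, "total"],
                     h2[s, "n_called"], a2[s, "alt"] / a2[s, "total"],
                     h1[s, "het"] / h1[s, "n_called"],
                     h2[s, "het"] / h2[s, "n_called"])
      expect_equal(unname(comp[s, ]), unname(o), tolerance = 1e-12)
    }
  }
})

test_that("FST analytic limits hold", {
  # identical allele frequencies and sizes -> FST <= 0 (~ 0)
  c_same <- cbind(ref = 4, alt = 4, total = 8)
  expect_lte(wc_fst(c_same, c_same)$weighted, 0)
  # fixed difference, no within-population variation -> FST = 1
  cA <- cbind(ref = 8, alt = 0, total = 8)
  cB <- cbind(ref = 0, alt = 8, total = 8)
  expect_equal(wc_fst(cA, cB)$weighted, 1, tolerance = 1e-12)
  # no usable sites -> NA sentinel
  c0 <- cbind(ref = 0, alt = 0, total = 0)
  expect_true(is.na(wc_fst(c0, c0)$weighted))
})

test_that("dxy matches definition, oracle, and limits", {
  c1 <- cbind(ref = 2, alt = 2, total = 4)   # p1 = 0.5
  c2 <- cbind(ref = 3, alt = 1, total = 4)   # p2 = 0.25
  expect_equal(dxy(c1, c2, 100), (0.5 * 0.75 + 0.5 * 0.25) / 100) # 0.005
  # one fixed difference in 100 bp -> 0.01
  expect_equal(dxy(cbind(ref = 4, alt = 0, total = 4),
                   cbind(ref = 0, alt = 4, total = 4), 100), 0.01)
  # identical monomorphic populations -> 0
  expect_equal(dxy(cbind(ref = 4, alt = 0, total = 4),
                   cbind(ref = 4, alt = 0, total = 4), 100), 0)
  expect_error(dxy(c1, c2, 0), "> 0")
  # oracle equivalence over random matrices
  set.seed(13)
  for (i in 1:5) {
    gm <- random_gm(50, 8, miss = 0.05)
    p1 <- gm$samples[1:4]; p2 <- gm$samples[5:8]
    expect_equal(dxy(allele_counts(gm, p1), allele_counts(gm, p2), 1e4),
                 oracle_dxy(gm, p1, p2, 1e4), tolerance = 1e-12)
  }
  # dxy of a population with itself = pi without the n/(n-1) correction
  set.seed(14)
  gm <- random_gm(30, 6)
  ac <- allele_counts(gm)
  p <- ac[, "alt"] / ac[, "total"]
  expect_equal(dxy(ac, ac, 1e4), sum(2 * p * (1 - p)) / 1e4,
               tolerance = 1e-12)
})

test_that("fixed_sites counts disjoint allele sets only", {
  # 5-site fixture, disjoint at sites 2 and 4
  g1 <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(2L, 2L), c(0L, 1L))
  g2 <- rbind(c(0L, 0L), c(2L, 2L), c(1L, 0L), c(0L, 0L), c(2L, 2L))
  gm <- toy_gm(cbind(g1, g2))
  c1 <- allele_counts(gm, gm$samples[1:2])
  c2 <- allele_counts(gm, gm$samples[3:4])
  expect_equal(fixed_sites(c1, c2), 2L)
  # shared polymorphism -> 0; heterozygote blocks fixation
  expect_equal(fixed_sites(cbind(ref = 1, alt = 3, total = 4),
                           cbind(ref = 0, alt = 4, total = 4)), 0L)
  expect_equal(fixed_sites(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("ref", "alt", "total"))),
                           matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("ref", "alt", "total")))),
               0L)
})

test_that("window_stats assembles per-window columns consistently", {
  set.seed(21)
  gm <- random_gm(200, 8, chrom_len = 1000L)
  pops <- list(a = gm$samples[1:4], b = gm$samples[5:8])
  ws <- window_stats(gm, pops, size = 250)
  expect_equal(nrow(ws), 4L)
  expect_equal(sum(ws$n_snps), 200L)
  expect_true(all(ws$pi_a >= 0 & ws$pi_b >= 0 & ws$dxy >= 0))
  expect_true(all(ws$fs <= ws$n_snps))
  expect_true(all(ws$fst_weighted <= 1, na.rm = TRUE))
  # windowed pi equals the oracle restricted to the window
  for (i in 1:4) {
    in_w <- gm$pos > ws$start[i] & gm$pos <= ws$end[i]
    sub <- gm_subset(gm, sites = in_w)
    expect_equal(ws$pi_a[i], oracle_pi(sub, pops$a, ws$end[i] - ws$start[i]),
                 tolerance = 1e-12)
  }
  # pooled pi >= mean of within-population pi
  wsp <- window_stats(gm, list(all = gm$samples), size = 250)
  expect_true(all(wsp$pi_all >= (ws$pi_a + ws$pi_b) / 2 - 1e-12))
})

test_that("whole_matrix_stats treats the molecule as one window", {
  # haploid, 2 samples differing at 1 of 1000 positions
  gm <- toy_gm(rbind(c(0L, 1L)), chrom_len = 1000L, ploidy = 1L)
  st <- whole_matrix_stats(gm, list(all = gm$samples))
  expect_equal(st$pi_all, 0.001)
  expect_equal(st$S_all, 1)
  # monomorphic -> pi 0, S 0, D undefined
  gm0 <- toy_gm(rbind(c(0L, 0L)), chrom_len = 1000L, ploidy = 1L)
  st0 <- whole_matrix_stats(gm0, list(all = gm0$samples))
  expect_equal(st0$pi_all, 0)
  expect_equal(st0$S_all, 0)
  expect_true(is.na(st0$D_all))
  # 5 haplotypes: pi equals brute force over C(5,2) pairs
  set.seed(31)
  g <- matrix(sample(0:1, 40 * 5, replace = TRUE), 40, 5)
  gm5 <- toy_gm(g, chrom_len = 2000L, ploidy = 1L)
  st5 <- whole_matrix_stats(gm5, list(all = gm5$samples))
  expect_equal(st5$pi_all, oracle_pi(gm5, gm5$samples, 2000),
               tolerance = 1e-12)
})

test_that("weighted W&C FST tracks Hudson's estimator on symmetric data", {
  sim <- simulate_divergence(split_cfg(10000), seed = 5)
  gm <- sim$nuclear
  p1 <- grep("sp1", gm$samples, value = TRUE)
  p2 <- grep("sp2", gm$samples, value = TRUE)
  a1 <- allele_counts(gm, p1); a2 <- allele_counts(gm, p2)
  wc <- wc_fst(a1, a2, het_counts(gm, p1), het_counts(gm, p2))$weighted
  f1 <- a1[, "alt"] / a1[, "total"]; f2 <- a2[, "alt"] / a2[, "total"]
  n1 <- a1[, "total"]; n2 <- a2[, "total"]
  num <- (f1 - f2)^2 - f1 * (1 - f1) / (n1 - 1) - f2 * (1 - f2) / (n2 - 1)
  den <- f1 * (1 - f2) + f2 * (1 - f1)
  hudson <- sum(num) / sum(den)
  expect_lt(abs(wc - hudson), 0.02)
})

test_that("undefined statistics are written as NA tokens, never 0", {
  gm <- toy_gm(rbind(c(0L, 0L, 0L, 0L)), chrom_len = 200L)
  ws <- window_stats(gm, list(a = gm$samples[1:2], b = gm$samples[3:4]),
                     size = 100)
  expect_true(is.na(ws$D_a[1]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_window_stats(ws, path, header = "provenance line")
  txt <- readLines(path)
  expect_match(txt[1], "^# provenance")
  expect_true(any(grepl("\tNA", txt)))
})
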