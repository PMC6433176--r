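test_that("bin_chromosome produces the scan geometry", {
  b <- bin_chromosome(10, 3)
  expect_equal(b$end - b$start, c(4, 3, 3))
  expect_equal(b$start[1], 0)
  expect_equal(b$end[3], 10)
  expect_equal(nrow(bin_chromosome(5e6, 2000)), 2000L)
  # 7 chromosomes x 2000 bins = 14000
  total <- sum(vapply(rep(5e6, 7), function(L) nrow(bin_chromosome(L, 2000)),
                      numeric(1)))
  expect_equal(total, 14000)
  expect_error(bin_chromosome(10, 11), "more bins")
  expect_error(bin_chromosome(10, 0), ">= 1")
})

test_that("background_sfs is the normalized empirical spectrum", {
  sf <- list(count = c(1L, 1L, 1L), n = 8L, folded = TRUE)
  expect_equal(unname(background_sfs(sf)), c(1, 0, 0, 0)) # all singletons
  sf2 <- list(count = rep(1:4, each = 5), n = 8L, folded = TRUE)
  expect_equal(unname(background_sfs(sf2)), rep(0.25, 4))  # uniform
  # 100-site fixture equals hand tally / 100
  set.seed(3)
  cnt <- sample(1:4, 100, replace = TRUE)
  sf3 <- list(count = cnt, n = 8L, folded = TRUE)
  expect_equal(unname(background_sfs(sf3)),
               unname(table(factor(cnt, 1:4))) / 100, ignore_attr = TRUE)
  expect_error(background_sfs(list(count = integer(0), n = 8L,
                                   folded = TRUE)), "no polymorphic")
})

test_that("site_frequencies folds and drops incomplete or fixed sites", {
  g <- rbind(c(2L, 2L, 2L, 2L),   # fixed in sample -> dropped
             c(0L, 0L, 0L, 1L),   # alt count 1
             c(2L, 2L, 1L, 2L),   # alt count 7 -> folded 1
             c(NA, 1L, 1L, 1L))   # incomplete -> dropped
  gm <- toy_gm(g)
  sf <- site_frequencies(gm, gm$samples)
  expect_equal(sf$n, 8L)
  expect_equal(sf$count, c(1L, 1L))
  expect_equal(sf$pos, gm$pos[2:3])
})

test_that("CLR collapses to zero on the null grid and is non-negative", {
  set.seed(4)
  sim <- simulate_divergence(neutral_cfg(c(chr1 = 1e6)), seed = 19)
  gm <- sim$nuclear
  sf <- site_frequencies(gm, gm$samples)
  bg <- background_sfs(sf)
  model <- divscan:::sweep_model_table(bg, sf$n)
  sfc <- list(pos = sf$pos, count = sf$count)
  # alpha grid containing only 0 -> CLR = 0 exactly
  r0 <- clr_at(5e5, sfc, model, alpha_grid = 0)
  expect_identical(r0$clr, 0)
  # full grid -> CLR >= 0 everywhere
  for (tp in c(1e5, 5e5, 9e5)) {
    r <- clr_at(tp, sfc, model, alpha_grid = alpha_grid_default(2e5))
    expect_gte(r$clr, 0)
  }
  # no sites near the test position -> undefined sentinel
  r_far <- clr_at(5e9, sfc, model)
  expect_true(is.na(r_far$clr))
})

test_that("CLR is calibrated under the null spectrum", {
  # sites drawn from the background SFS itself: CLR < 5 in >= 95% of 100 reps
  set.seed(5)
  sim <- simulate_divergence(neutral_cfg(c(chr1 = 2e6)), seed = 23)
  gm <- sim$nuclear
  sf <- site_frequencies(gm, gm$samples)
  bg <- background_sfs(sf)
  model <- divscan:::sweep_model_table(bg, sf$n)
  classes <- as.integer(names(bg))
  clrs <- vapply(1:100, function(i) {
    pos <- sort(sample.int(4e5, 250))
    cnt <- sample(classes, 250, replace = TRUE, prob = bg)
    clr_at(2e5, list(pos = pos, count = cnt), model)$clr
  }, numeric(1))
  expect_gte(mean(clrs < 5), 0.95)
})

test_that("CLR is invariant to a shift of the coordinate origin", {
  sim <- simulate_divergence(neutral_cfg(c(chr1 = 1e6)), seed = 29)
  gm <- sim$nuclear
  sf <- site_frequencies(gm, gm$samples)
  model <- divscan:::sweep_model_table(background_sfs(sf), sf$n)
  sfc <- list(pos = sf$pos, count = sf$count)
  sfc_shift <- list(pos = sf$pos + 7777, count = sf$count)
  a <- clr_at(5e5, sfc, model)
  b <- clr_at(5e5 + 7777, sfc_shift, model)
  expect_equal(a$clr, b$clr, tolerance = 1e-12)
  expect_equal(a$alpha_hat, b$alpha_hat)
})

test_that("sweep_scan flags planted sweeps and handles empty chromosomes", {
  cfg <- neutral_cfg(c(chr1 = 2e6))
  sweeps <- list(sweep_config("chr1", 4e5, s = 0.01, species = "sp1"),
                 sweep_config("chr1", 1e6, s = 0.01, species = "sp1"),
                 sweep_config("chr1", 16e5, s = 0.01, species = "sp1"))
  sim <- simulate_divergence(cfg, sweeps, seed = 37)
  gm <- sim$nuclear
  sp1 <- grep("sp1", gm$samples, value = TRUE)
  sc <- sweep_scan(gm, sp1, n_bins = 200)
  expect_equal(nrow(sc), 200L)
  # >= 2 of the 3 planted sweeps recovered as flagged clusters
  hit <- vapply(c(4e5, 1e6, 16e5), function(p) {
    near <- abs((sc$bin_start + sc$bin_end) / 2 - p) < 1e5
    any(sc$is_sweep[near])
  }, logical(1))
  expect_gte(sum(hit), 2L)
  # monotone ladder: stronger sweep -> weakly larger max CLR near the site
  # (seed-averaged; a single realization is too noisy for a strict ladder)
  maxima <- vapply(c(0.002, 0.008, 0.03), function(s) {
    mean(vapply(41:43, function(seed) {
      simx <- simulate_divergence(neutral_cfg(c(chr1 = 2e6)),
                                  list(sweep_config("chr1", 1e6, s = s,
                                                    species = "sp1")),
                                  seed = seed)
      scx <- sweep_scan(simx$nuclear, sp1, n_bins = 100)
      near <- abs((scx$bin_start + scx$bin_end) / 2 - 1e6) < 3e5
      max(scx$clr[near], na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(maxima) >= 0))
})

test_that("a chromosome without polymorphism yields undefined sentinels", {
  g <- rbind(c(0L, 1L, 1L, 2L))
  gm <- genotype_matrix(c("chr1"), 50L, "A", "T", g,
                        sprintf("s%d", 1:4), 2L,
                        c(chr1 = 1000L, chr2 = 1000L))
  sc <- sweep_scan(gm, gm$samples, n_bins = 10, flank = 1e4)
  expect_true(all(is.na(sc$clr[sc$chrom == "chr2"])))
  expect_false(any(sc$is_sweep[sc$chrom == "chr2"]))
})
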