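# Fixtures are built in code at test time; nothing binary ships with the
# package.

vcf_header <- function(contigs = c(chr1 = 500000L), samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_record <- function(pos, ref, alt, mq, gts, dps, chrom = "chr1") {
  paste(c(chrom, pos, ".", ref, alt, "50", "PASS", sprintf("MQ=%g", mq),
          "GT:DP", paste(gts, dps, sep = ":")), collapse = "\t")
}

# 10-record fixture: 3 SNPs + 2 INDELs + 5 further SNPs (one triallelic).
# Exactly 4 records have MQ <= 20; exactly 5 are biallelic SNPs with
# MQ > 20 (one of them carries a DP = 3 genotype and one a ./. call).
write_fixture_vcf <- function(path) {
  recs <- c(
    vcf_record(100, "A", "T", 50, c("0/1", "0/0"), c(10, 12)),   # pass
    vcf_record(200, "G", "C", 20, c("0/0", "1/1"), c(10, 10)),   # MQ == 20
    vcf_record(300, "T", "A", 18, c("0/1", "0/1"), c(10, 10)),   # low MQ
    vcf_record(400, "A", "AT", 10, c("0/1", "0/0"), c(10, 10)),  # indel, low
    vcf_record(500, "CT", "C", 20, c("0/0", "0/1"), c(10, 10)),  # indel, low
    vcf_record(600, "G", "T,A", 50, c("1/2", "0/0"), c(10, 10)), # triallelic
    vcf_record(700, "C", "G", 35, c("1/1", "0/1"), c(10, 10)),   # pass
    vcf_record(800, "T", "C", 40, c("0/1", "./."), c(10, 2)),    # pass, miss
    vcf_record(900, "A", "G", 25, c("0/0", "0/1"), c(10, 3)),    # pass, DP=3
    vcf_record(950, "G", "A", 60, c("1/1", "1/1"), c(10, 10)))   # pass
  writeLines(c(vcf_header(), recs), path)
  path
}

# genotype matrix built directly in code (diploid, no missing)
toy_gm <- function(geno, chrom_len = 1000L, ploidy = 2L,
                   pos = NULL, chrom = "chr1") {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  genotype_matrix(rep(chrom, n), pos, rep("A", n), rep("T", n), geno,
                  sprintf("s%d", seq_len(ncol(geno))), ploidy,
                  stats::setNames(chrom_len, chrom))
}

# random diploid matrix with optional missingness, seeded by caller
random_gm <- function(n_sites, n_samples, chrom_len = 1e4L, miss = 0) {
  g <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  if (miss > 0) g[runif(length(g)) < miss] <- NA_integer_
  toy_gm(g, chrom_len, pos = sort(sample.int(chrom_len, n_sites)))
}

# Brute-force oracles: expand each site into its multiset of alleles and
# average pairwise differences directly.  Independent of the package's
# count-based formulas.
site_alleles <- function(gm, samples) {
  idx <- match(samples, gm$samples)
  lapply(seq_along(gm$pos), function(s) {
    g <- gm$geno[s, idx]
    g <- g[!is.na(g)]
    if (gm$ploidy == 1L) g else unlist(lapply(g, function(d)
      c(rep(1L, d), rep(0L, gm$ploidy - d))))
  })
}

oracle_khat <- function(gm, samples) {
  sum(vapply(site_alleles(gm, samples), function(al) {
    n <- length(al)
    if (n < 2) return(0)
    diff <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      diff <- diff + (al[i] != al[j])
    diff / choose(n, 2)
  }, numeric(1)))
}

oracle_pi <- function(gm, samples, L) oracle_khat(gm, samples) / L

oracle_dxy <- function(gm, samples1, samples2, L) {
  a1 <- site_alleles(gm, samples1)
  a2 <- site_alleles(gm, samples2)
  tot <- 0
  for (s in seq_along(a1)) {
    x <- a1[[s]]; y <- a2[[s]]
    if (!length(x) || !length(y)) next
    diff <- 0
    for (i in seq_along(x)) for (j in seq_along(y))
      diff <- diff + (x[i] != y[j])
    tot <- tot + diff / (length(x) * length(y))
  }
  tot / L
}

# Independent Tajima (1989) evaluation, written directly from the constants
oracle_tajima <- function(derived_counts, n) {
  S <- length(derived_counts)
  k <- sum(2 * derived_counts * (n - derived_counts) / (n * (n - 1)))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Independent Weir & Cockerham (1984) components for one biallelic site,
# two populations, written from the published formulas (haploid h = 0)
oracle_wc <- function(n1, p1, n2, p2, h1 = 0, h2 = 0) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

neutral_cfg <- function(chrom_lengths = c(chr1 = 2e6), n1 = 8, n2 = 8) {
  demography_config(t_split = 0, bottleneck = NULL, migration = 0,
                    t_contact = 0, n_hybrids = 0, n_sample_sp1 = n1,
                    n_sample_sp2 = n2, chrom_lengths = chrom_lengths)
}

split_cfg <- function(t_split, chrom_lengths = c(chr1 = 2e6), n1 = 8, n2 = 8,
                      migration = 0, t_contact = 0, n_hybrids = 0, ...) {
  demography_config(t_split = t_split, bottleneck = NULL,
                    migration = migration, t_contact = t_contact,
                    n_hybrids = n_hybrids, n_sample_sp1 = n1,
                    n_sample_sp2 = n2, chrom_lengths = chrom_lengths, ...)
}
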