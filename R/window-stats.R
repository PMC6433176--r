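#' Tile chromosomes into non-overlapping windows
#'
#' Standard genome-scan tiling: fixed-size windows laid end to end; the
#' terminal window of each chromosome may be shorter.  Coordinates are
#' 0-based half-open (BED convention); VCF positions are converted when sites
#' are assigned to windows.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp (default 100 kb).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size = 1e5) {
  if (size <= 0) stop("window size must be > 0")
  if (any(chrom_lengths == 0)) {
    warning("zero-length chromosome(s) produce no windows")
    chrom_lengths <- chrom_lengths[chrom_lengths > 0]
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, len))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Nucleotide diversity from per-site allele counts
#'
#' \eqn{\pi = (1/L)\sum_s [n_s/(n_s-1)]\, 2 p_s (1-p_s)} with \eqn{n_s} the
#' called alleles and \eqn{p_s} the alternate-allele frequency at site `s`.
#' This is the mean pairwise difference per bp with the full region length as
#' denominator (the `--window-pi` convention): invariant and uncalled
#' positions contribute 0 to the numerator but are part of `L`.  Sites with
#' fewer than 2 called alleles are skipped.
#'
#' @param counts matrix from [allele_counts()] restricted to the region.
#' @param L region length in bp.
#' @return per-bp diversity (scalar).
#' @export
nucleotide_diversity <- function(counts, L) {
  if (L <= 0) stop("region length must be > 0")
  khat_from_counts(counts) / L
}

#' Mean pairwise differences (absolute) from allele counts
#'
#' \eqn{\hat k = \sum_s 2\, r_s a_s / (n_s (n_s - 1))}: the average number of
#' differences over all pairs of called alleles, summed over sites.
#'
#' @param counts matrix from [allele_counts()].
#' @return scalar.
#' @export
khat_from_counts <- function(counts) {
  n <- counts[, "total"]
  ok <- n >= 2
  sum(2 * counts[ok, "ref"] * counts[ok, "alt"] / (n[ok] * (n[ok] - 1)))
}

#' Count segregating sites from allele counts
#' @param counts matrix from [allele_counts()].
#' @return integer count of polymorphic sites (both alleles observed).
#' @export
segregating_sites <- function(counts) {
  sum(counts[, "alt"] > 0 & counts[, "ref"] > 0 & counts[, "total"] >= 2)
}

#' Tajima's D from allele counts
#'
#' Standard normalized difference between the pairwise and Watterson
#' estimators of theta, with the 1989 constants.  With missing data the
#' sample size `n` varies across sites; following the documented windowing
#' rule, `n` is the median called-allele count over polymorphic sites and
#' sites deviating from it by more than 20% are excluded.  `S = 0` (or
#' `n < 4`) yields `NA`, never 0.
#'
#' @param counts matrix from [allele_counts()] restricted to the window.
#' @param n optionally force the per-site sample size (overrides the median
#'   rule; used when data are complete).
#' @return Tajima's D (scalar, `NA` when undefined).
#' @export
tajimas_d <- function(counts, n = NULL) {
  poly <- counts[, "alt"] > 0 & counts[, "ref"] > 0 & counts[, "total"] >= 2
  counts <- counts[poly, , drop = FALSE]
  if (!nrow(counts)) return(NA_real_)
  if (is.null(n)) {
    n <- round(stats::median(counts[, "total"]))
    keep <- abs(counts[, "total"] - n) <= 0.2 * n
    counts <- counts[keep, , drop = FALSE]
  } else {
    counts <- counts[counts[, "total"] == n, , drop = FALSE]
  }
  S <- nrow(counts)
  if (S == 0L || n < 4) return(NA_real_)
  k <- khat_from_counts(counts)
  cst <- tajima_constants(n)
  denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (k - S / cst$a1) / denom
}

#' Weir-Cockerham FST variance components for two populations
#'
#' Per-site `a` (between-population), `b` (between individuals within
#' populations) and `c` (within-individual) variance components of Weir &
#' Cockerham (1984) for a biallelic site and r = 2 populations, using
#' observed heterozygote frequencies.  For haploid data pass `het = 0`.
#'
#' @param counts1,counts2 matrices from [allele_counts()] for each
#'   population.
#' @param het1,het2 matrices from [het_counts()] (heterozygote and called
#'   genotype counts); defaults assume no heterozygotes (haploid).
#' @return matrix with columns `a`, `b`, `c` (one row per site; `NA` rows
#'   where a population has < 2 called alleles).
#' @export
wc_components <- function(counts1, counts2, het1 = NULL, het2 = NULL) {
  # sample sizes in individuals (diploid) or sequences (haploid)
  n1g <- if (!is.null(het1)) het1[, "n_called"] else counts1[, "total"]
  n2g <- if (!is.null(het2)) het2[, "n_called"] else counts2[, "total"]
  h1 <- if (!is.null(het1)) het1[, "het"] / pmax(n1g, 1) else 0
  h2 <- if (!is.null(het2)) het2[, "het"] / pmax(n2g, 1) else 0
  p1 <- counts1[, "alt"] / counts1[, "total"]
  p2 <- counts2[, "alt"] / counts2[, "total"]
  r <- 2
  nbar <- (n1g + n2g) / r
  nc <- (r * nbar - (n1g^2 + n2g^2) / (r * nbar)) / (r - 1)
  pbar <- (n1g * p1 + n2g * p2) / (r * nbar)
  s2 <- (n1g * (p1 - pbar)^2 + n2g * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1g * h1 + n2g * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- counts1[, "total"] < 2 | counts2[, "total"] < 2
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  cbind(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST
#'
#' The primary value is the ratio-of-sums ("weighted") estimator
#' \eqn{\sum a / \sum (a+b+c)}; the mean of per-site ratios is reported as a
#' secondary value.  Negative estimates are reported as computed, never
#' clamped; windows with no usable site yield `NA`.
#'
#' @inheritParams wc_components
#' @return list with `weighted`, `mean`, and the per-site `components`
#'   matrix.
#' @export
wc_fst <- function(counts1, counts2, het1 = NULL, het2 = NULL) {
  comp <- wc_components(counts1, counts2, het1, het2)
  tot <- rowSums(comp)
  usable <- !is.na(tot) & tot > 0
  if (!any(usable)) return(list(weighted = NA_real_, mean = NA_real_,
                                components = comp))
  list(weighted = sum(comp[usable, "a"]) / sum(tot[usable]),
       mean = mean(comp[usable, "a"] / tot[usable]),
       components = comp)
}

#' Absolute divergence Dxy
#'
#' \eqn{D_{xy} = (1/L)\sum_s [p_{1s}(1-p_{2s}) + (1-p_{1s})p_{2s}]}: the
#' average per-bp difference between one sequence drawn from each
#' population.  Invariant and uncalled positions contribute 0 to the
#' numerator while `L` remains the full region length.
#'
#' @inheritParams wc_components
#' @param L region length in bp.
#' @return per-bp divergence (scalar).
#' @export
dxy <- function(counts1, counts2, L) {
  if (L <= 0) stop("region length must be > 0")
  ok <- counts1[, "total"] > 0 & counts2[, "total"] > 0
  p1 <- counts1[ok, "alt"] / counts1[ok, "total"]
  p2 <- counts2[ok, "alt"] / counts2[ok, "total"]
  sum(p1 * (1 - p2) + (1 - p1) * p2) / L
}

#' Count fixation sites (Fs)
#'
#' A fixation site is one where the two populations carry disjoint allele
#' sets: each population fixed, for different alleles.  A population with a
#' heterozygote carries both alleles and is never fixed, so such sites never
#' count.  Sites uncalled in either population are skipped.
#'
#' @inheritParams wc_components
#' @return integer count.
#' @export
fixed_sites <- function(counts1, counts2) {
  ok <- counts1[, "total"] > 0 & counts2[, "total"] > 0
  sum((counts1[ok, "alt"] == 0 & counts2[ok, "ref"] == 0) |
      (counts1[ok, "ref"] == 0 & counts2[ok, "alt"] == 0))
}

#' Per-window diversity and divergence statistics
#'
#' Computes, for every non-overlapping window: per-population nucleotide
#' diversity, segregating sites and Tajima's D, plus (for the first two
#' populations) Weir-Cockerham FST (weighted and mean-of-ratios),
#' absolute divergence Dxy and the fixation-site count Fs.
#'
#' @param gm a `genotype_matrix` whose `chrom_lengths` are set.
#' @param populations named list of sample-name vectors; names become column
#'   suffixes.
#' @param size window size in bp (default 100 kb).
#' @param windows optional precomputed window table from [make_windows()].
#' @return data.frame (one row per window) with BED-compatible first three
#'   columns; undefined statistics are `NA`.
#' @export
window_stats <- function(gm, populations, size = 1e5, windows = NULL) {
  if (is.null(gm$chrom_lengths))
    stop("genotype matrix lacks chrom_lengths; cannot tile windows")
  if (is.null(names(populations)) || any(!nzchar(names(populations))))
    stop("populations must be a named list")
  if (is.null(windows)) windows <- make_windows(gm$chrom_lengths, size)
  wkey <- paste0(windows$chrom, ":", windows$start)
  skey <- paste0(gm$chrom, ":", floor((gm$pos - 1) / size) * size)
  widx <- match(skey, wkey)                 # window of each site
  site_sets <- split(seq_along(gm$pos), factor(widx, seq_len(nrow(windows))))
  cnts <- lapply(populations, function(p) allele_counts(gm, p))
  hets <- if (gm$ploidy == 2L)
    lapply(populations, function(p) het_counts(gm, p)) else
    lapply(populations, function(p) NULL)
  L <- windows$end - windows$start
  out <- windows
  out$n_snps <- lengths(site_sets)
  for (nm in names(populations)) {
    cc <- cnts[[nm]]
    out[[paste0("pi_", nm)]] <- vapply(seq_along(site_sets), function(i) {
      nucleotide_diversity(cc[site_sets[[i]], , drop = FALSE], L[i])
    }, numeric(1))
    out[[paste0("S_", nm)]] <- vapply(site_sets, function(s) {
      segregating_sites(cc[s, , drop = FALSE])
    }, numeric(1))
    out[[paste0("D_", nm)]] <- vapply(site_sets, function(s) {
      tajimas_d(cc[s, , drop = FALSE])
    }, numeric(1))
  }
  if (length(populations) >= 2L) {
    c1 <- cnts[[1]]; c2 <- cnts[[2]]
    h1 <- hets[[1]]; h2 <- hets[[2]]
    fst_w <- fst_m <- dxy_v <- rep(NA_real_, nrow(windows))
    fs_v <- integer(nrow(windows))
    for (i in seq_along(site_sets)) {
      s <- site_sets[[i]]
      f <- wc_fst(c1[s, , drop = FALSE], c2[s, , drop = FALSE],
                  if (is.null(h1)) NULL else h1[s, , drop = FALSE],
                  if (is.null(h2)) NULL else h2[s, , drop = FALSE])
      fst_w[i] <- f$weighted; fst_m[i] <- f$mean
      dxy_v[i] <- dxy(c1[s, , drop = FALSE], c2[s, , drop = FALSE], L[i])
      fs_v[i] <- fixed_sites(c1[s, , drop = FALSE], c2[s, , drop = FALSE])
    }
    out$fst_weighted <- fst_w
    out$fst_mean <- fst_m
    out$dxy <- dxy_v
    out$fs <- fs_v
  }
  out
}

#' Whole-matrix statistics (single window spanning the molecule)
#'
#' Used for short non-recombining molecules such as the ~129 kb chloroplast,
#' which is treated as a single matrix rather than tiled into windows.
#'
#' @inheritParams window_stats
#' @param L total reference length of the molecule; defaults to the sum of
#'   `chrom_lengths`.
#' @return one-row data.frame in the [window_stats()] layout.
#' @export
whole_matrix_stats <- function(gm, populations, L = NULL) {
  if (is.null(L)) {
    if (is.null(gm$chrom_lengths))
      stop("need L or chrom_lengths")
    L <- sum(gm$chrom_lengths)
  }
  cl <- stats::setNames(L, if (length(unique(gm$chrom)) == 1L)
    unique(gm$chrom) else "molecule")
  gm2 <- gm
  gm2$chrom_lengths <- cl
  if (length(unique(gm$chrom)) > 1L) gm2$chrom <- rep("molecule",
                                                      length(gm$chrom))
  window_stats(gm2, populations, size = L)
}

#' Write a window-statistics table as TSV
#'
#' BED-compatible first three columns; undefined values are written as the
#' literal `NA` token, never 0.
#'
#' @param ws data.frame from [window_stats()].
#' @param path output path.
#' @param header optional provenance comment lines (prefixed with `#`).
#' @export
write_window_stats <- function(ws, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(ws, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
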