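#' Divide a chromosome into near-equal scan bins
#'
#' `n_bins` contiguous bins tile the chromosome; widths differ by at most
#' 1 bp (the remainder is spread over the leftmost bins).  The composite
#' likelihood is evaluated at bin midpoints.
#'
#' @param chrom_length chromosome length in bp.
#' @param n_bins number of bins (default 2000).
#' @return data.frame with columns `start` (0-based), `end`, `mid`.
#' @export
bin_chromosome <- function(chrom_length, n_bins = 2000L) {
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_bins > chrom_length) stop("more bins than base pairs")
  w <- rep(floor(chrom_length / n_bins), n_bins)
  extra <- chrom_length - sum(w)
  if (extra > 0) w[seq_len(extra)] <- w[seq_len(extra)] + 1L
  end <- cumsum(w)
  start <- c(0, end[-n_bins])
  data.frame(start = start, end = end, mid = (start + end) / 2)
}

#' Extract site frequencies for one population
#'
#' Returns folded minor-allele counts at sites fully called in the
#' population (uniform sample size `n`, required by the spectrum model);
#' only polymorphic sites are kept.  Without outgroup polarization the
#' folded spectrum is the honest default.
#'
#' @param gm a `genotype_matrix`.
#' @param population character vector of sample names.
#' @param folded fold the spectrum (default TRUE).
#' @return list with `chrom`, `pos`, `count`, `n`.
#' @export
site_frequencies <- function(gm, population, folded = TRUE) {
  cnt <- allele_counts(gm, population)
  n <- max(cnt[, "total"])
  ok <- cnt[, "total"] == n & cnt[, "alt"] > 0 & cnt[, "ref"] > 0
  count <- cnt[ok, "alt"]
  if (folded) count <- pmin(count, n - count)
  list(chrom = gm$chrom[ok], pos = gm$pos[ok],
       count = as.integer(count), n = as.integer(n), folded = folded)
}

#' Background (genome-wide) site frequency spectrum
#'
#' Empirical spectrum over polymorphic sites, normalized to sum 1.
#'
#' @param sf output of [site_frequencies()].
#' @return named probability vector over frequency classes (1..n-1, or
#'   1..floor(n/2) folded).
#' @export
background_sfs <- function(sf) {
  if (!length(sf$count)) stop("no polymorphic sites")
  classes <- if (sf$folded) seq_len(floor(sf$n / 2)) else seq_len(sf$n - 1L)
  tab <- tabulate(sf$count, nbins = max(classes))[classes]
  stats::setNames(tab / sum(tab), classes)
}

# Sweep sampling tensor F[k+1, j, e+1]: probability that a post-sweep sample
# of n lineages carries k derived alleles, given pre-sweep derived count j
# and e escaped lineages.  Escaped lineages are drawn without replacement
# from the pre-sweep sample; the swept block inherits one further draw.
# At e = n the sample is the pre-sweep sample itself, which makes the model
# collapse exactly onto the background as the escape probability tends to 1.
sweep_tensor <- function(n) {
  F <- array(0, dim = c(n + 1L, n - 1L, n + 1L))
  for (j in seq_len(n - 1L)) {
    for (e in 0:n) {
      if (e == n) {
        F[j + 1L, j, e + 1L] <- 1
      } else {
        a <- 0:e
        pa <- stats::dhyper(a, j, n - j, e)
        p_rep1 <- (j - a) / (n - e)        # swept representative derived
        k1 <- a + (n - e)                  # representative derived
        k0 <- a                            # representative ancestral
        for (i in seq_along(a)) {
          F[k1[i] + 1L, j, e + 1L] <- F[k1[i] + 1L, j, e + 1L] +
            pa[i] * p_rep1[i]
          F[k0[i] + 1L, j, e + 1L] <- F[k0[i] + 1L, j, e + 1L] +
            pa[i] * (1 - p_rep1[i])
        }
      }
    }
  }
  F
}

# Model table: log P(folded class | p_e) for a grid of escape probabilities.
# Returns list(log_m = K x n_pe matrix, pe_grid, log_bg = K vector).
sweep_model_table <- function(bg, n, n_pe = 101L) {
  K <- length(bg)
  folded_classes <- as.integer(names(bg))
  # symmetric unfolding of the folded background
  u <- numeric(n - 1L)
  for (i in seq_along(folded_classes)) {
    j <- folded_classes[i]
    if (j == n - j) u[j] <- bg[i]
    else { u[j] <- bg[i] / 2; u[n - j] <- bg[i] / 2 }
  }
  F <- sweep_tensor(n)
  Fm <- matrix(F, nrow = (n + 1L) * (n - 1L))   # (k,j) x e
  pe_grid <- seq(0, 1, length.out = n_pe)
  log_m <- matrix(NA_real_, K, n_pe)
  for (g in seq_len(n_pe)) {
    w <- stats::dbinom(0:n, n, pe_grid[g])
    Pkj <- matrix(Fm %*% w, nrow = n + 1L)      # k x j
    Pk <- as.numeric(Pkj %*% u)                 # over k = 0..n
    poly <- Pk[2:n]                             # condition on polymorphism
    # at p_e = 0 every lineage is swept and polymorphism has probability 0;
    # leave the column at the floor so the null (alpha = 0) dominates there
    poly <- if (sum(poly) > 0) poly / sum(poly) else rep(0, n - 1L)
    folded <- vapply(folded_classes, function(j) {
      if (j == n - j) poly[j] else poly[j] + poly[n - j]
    }, numeric(1))
    log_m[, g] <- log(pmax(folded, 1e-300))
  }
  list(log_m = log_m, pe_grid = pe_grid,
       log_bg = log(pmax(as.numeric(bg), 1e-300)),
       classes = folded_classes)
}

#' Default sweep-strength grid
#'
#' `alpha` is the characteristic physical scale (bp) of the sweep footprint:
#' the probability that a lineage at distance `d` escapes the sweep is
#' `1 - exp(-d / alpha)`.  `alpha = 0` is the neutral null (everything
#' escapes; the model is the background itself), so the composite likelihood
#' ratio is non-negative by construction.  The default grid spans
#' effectively-neutral to flank-scale footprints.
#'
#' @param flank composite-likelihood neighbourhood half-width in bp.
#' @param k number of non-null grid points (default 15).
#' @return numeric vector including exact 0.
#' @export
alpha_grid_default <- function(flank = 2e5, k = 15L) {
  c(0, exp(seq(log(flank / 200), log(2 * flank), length.out = k)))
}

#' Composite likelihood ratio at one test position
#'
#' CLR = 2 [max_alpha l_sweep(alpha) - l_background] over sites within the
#' flank, using the escape-probability distortion of the background spectrum
#' (lineages escape the sweep with probability `1 - exp(-d/alpha)`).
#'
#' @param test_pos test position in bp.
#' @param sf [site_frequencies()] for one chromosome.
#' @param model table from `sweep_model_table` (built by [sweep_scan()]).
#' @param alpha_grid sweep-scale grid, must contain 0.
#' @param flank neighbourhood half-width in bp.
#' @return list `clr`, `alpha_hat` (`NA` when no site is in range).
#' @export
clr_at <- function(test_pos, sf, model, alpha_grid = alpha_grid_default(),
                   flank = 2e5) {
  in_rng <- which(sf$pos >= test_pos - flank & sf$pos <= test_pos + flank)
  if (!length(in_rng)) return(list(clr = NA_real_, alpha_hat = NA_real_))
  k_idx <- match(sf$count[in_rng], model$classes)
  d <- abs(sf$pos[in_rng] - test_pos)
  ll0 <- sum(model$log_bg[k_idx])
  n_pe <- length(model$pe_grid)
  K <- nrow(model$log_m)
  best <- ll0; best_a <- 0
  for (a in alpha_grid) {
    if (a <= 0) next
    pe <- 1 - exp(-d / a)
    bin <- pmin(n_pe, as.integer(round(pe * (n_pe - 1L))) + 1L)
    ll <- sum(model$log_m[k_idx + (bin - 1L) * K])
    if (ll > best) { best <- ll; best_a <- a }
  }
  list(clr = 2 * (best - ll0), alpha_hat = best_a)
}

#' Genome scan for selective sweeps (composite likelihood ratio)
#'
#' Each chromosome is divided into `n_bins` bins and the CLR is evaluated at
#' every bin midpoint against the genome-wide background spectrum of the
#' population.  Bins with CLR above `clr_threshold` are flagged as sweep
#' candidates.  Fixed and incompletely called sites are excluded; only
#' polymorphic frequency classes are modelled.
#'
#' @param gm a `genotype_matrix` with `chrom_lengths`.
#' @param population character vector of sample names.
#' @param n_bins bins per chromosome (default 2000).
#' @param clr_threshold sweep call threshold (default 20).
#' @param flank neighbourhood half-width in bp (default 200 kb).
#' @param alpha_grid sweep-scale grid including 0.
#' @param folded fold the spectrum (default TRUE).
#' @return data.frame with columns `chrom`, `bin_start`, `bin_end`, `clr`,
#'   `alpha_hat`, `is_sweep`.
#' @export
sweep_scan <- function(gm, population, n_bins = 2000L, clr_threshold = 20,
                       flank = 2e5, alpha_grid = alpha_grid_default(flank),
                       folded = TRUE) {
  if (is.null(gm$chrom_lengths)) stop("genotype matrix lacks chrom_lengths")
  if (!any(alpha_grid == 0)) alpha_grid <- c(0, alpha_grid)
  sf_all <- site_frequencies(gm, population, folded)
  out <- lapply(names(gm$chrom_lengths), function(ch) {
    bins <- bin_chromosome(gm$chrom_lengths[[ch]], n_bins)
    data.frame(chrom = ch, bin_start = bins$start, bin_end = bins$end,
               mid = bins$mid)
  })
  out <- do.call(rbind, out)
  out$clr <- NA_real_; out$alpha_hat <- NA_real_
  if (length(sf_all$count)) {
    bg <- background_sfs(sf_all)
    model <- sweep_model_table(bg, sf_all$n)
    for (ch in unique(out$chrom)) {
      on_ch <- sf_all$chrom == ch
      if (!any(on_ch)) next
      sf_ch <- list(pos = sf_all$pos[on_ch], count = sf_all$count[on_ch])
      rows <- which(out$chrom == ch)
      for (r in rows) {
        res <- clr_at(out$mid[r], sf_ch, model, alpha_grid, flank)
        out$clr[r] <- res$clr; out$alpha_hat[r] <- res$alpha_hat
      }
    }
  }
  out$is_sweep <- !is.na(out$clr) & out$clr > clr_threshold
  out$mid <- NULL
  out
}

#' Write a sweep-scan table as TSV
#' @param scan data.frame from [sweep_scan()].
#' @param path output path.
#' @param header optional provenance comment lines.
#' @export
write_sweep_scan <- function(scan, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(scan, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
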