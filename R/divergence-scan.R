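#' Empirical tail threshold for outlier windows
#'
#' Returns the value delimiting the lower or upper `q` tail of a window
#' statistic.  `NA` windows are excluded before ranking.  Ties at the
#' threshold are inclusive: all windows equal to the threshold belong to the
#' tail, so the tail may exceed `q * n` windows.
#'
#' @param values numeric vector of per-window statistics.
#' @param q tail mass (default 0.05).
#' @param tail `"lower"` or `"upper"`.
#' @return the threshold value.
#' @export
quantile_threshold <- function(values, q = 0.05, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  v <- values[!is.na(values)]
  if (!length(v)) stop("all values are NA")
  if (length(unique(v)) == 1L)
    warning("constant statistic: every window is tied at the threshold")
  k <- max(1L, floor(q * length(v)))
  s <- sort(v)
  if (tail == "lower") s[k] else s[length(v) - k + 1L]
}

#' Classify outlier windows into selection-candidate categories
#'
#' Implements the outlier-overlap rule used for genome scans of a species
#' pair: windows in the bottom `q` of nucleotide diversity within a species
#' are low-nucleotide-diversity (LND) candidates; windows in the top `q` of
#' interspecific FST are high-genetic-divergence (HIGD) windows.  A window
#' that is LND in one species only and HIGD is an adaptive-selection
#' candidate for that species; LND in both species plus HIGD marks divergent
#' selection; shared LND windows falling in the bottom `q` of FST are flagged
#' separately (low-divergence shared troughs).
#'
#' @param ws a [window_stats()] table containing `pi_<sp1>`, `pi_<sp2>` and
#'   `fst_weighted`.
#' @param species character vector of the two population names used in `ws`.
#' @param q tail mass for every threshold (default 0.05).
#' @return `ws` with logical columns `lnd_<sp1>`, `lnd_<sp2>`, `higd`,
#'   `ligd` and a `category` factor; attributes `thresholds` and `summary`
#'   carry the cutoffs and the narrative counts.
#' @export
classify_outliers <- function(ws, species, q = 0.05) {
  stopifnot(length(species) == 2L)
  pi1 <- ws[[paste0("pi_", species[1])]]
  pi2 <- ws[[paste0("pi_", species[2])]]
  fst <- ws$fst_weighted
  if (is.null(pi1) || is.null(pi2) || is.null(fst))
    stop("window table lacks pi_<species> or fst_weighted columns")
  thr <- list(pi1 = quantile_threshold(pi1, q, "lower"),
              pi2 = quantile_threshold(pi2, q, "lower"),
              fst_hi = quantile_threshold(fst, q, "upper"),
              fst_lo = quantile_threshold(fst, q, "lower"))
  lnd1 <- !is.na(pi1) & pi1 <= thr$pi1
  lnd2 <- !is.na(pi2) & pi2 <= thr$pi2
  higd <- !is.na(fst) & fst >= thr$fst_hi
  ligd <- !is.na(fst) & fst <= thr$fst_lo
  category <- rep("none", nrow(ws))
  category[lnd1 & lnd2 & ligd] <- "shared_lnd_low_divergence"
  category[lnd1 & higd & !lnd2] <- paste0("adaptive_candidate_", species[1])
  category[lnd2 & higd & !lnd1] <- paste0("adaptive_candidate_", species[2])
  category[lnd1 & lnd2 & higd] <- "divergent_candidate"
  out <- ws
  out[[paste0("lnd_", species[1])]] <- lnd1
  out[[paste0("lnd_", species[2])]] <- lnd2
  out$higd <- higd
  out$ligd <- ligd
  out$category <- category
  attr(out, "thresholds") <- thr
  attr(out, "summary") <- list(
    n_windows = nrow(ws),
    n_lnd = stats::setNames(c(sum(lnd1), sum(lnd2)), species),
    n_lnd_shared = sum(lnd1 & lnd2),
    n_lnd_specific = stats::setNames(c(sum(lnd1 & !lnd2), sum(lnd2 & !lnd1)),
                                     species),
    n_higd = sum(higd),
    n_adaptive = stats::setNames(
      c(sum(lnd1 & higd & !lnd2), sum(lnd2 & higd & !lnd1)), species),
    n_divergent = sum(lnd1 & lnd2 & higd),
    n_shared_lnd_low_fst = sum(lnd1 & lnd2 & ligd))
  out
}

#' Narrative summary of an outlier classification
#' @param x output of [classify_outliers()].
#' @return character vector of summary lines.
#' @export
outlier_summary <- function(x) {
  s <- attr(x, "summary")
  thr <- attr(x, "thresholds")
  sp <- names(s$n_lnd)
  c(sprintf("windows: %d", s$n_windows),
    sprintf("thresholds: pi(%s) < %.6g, pi(%s) < %.6g, FST > %.6g, FST < %.6g",
            sp[1], thr$pi1, sp[2], thr$pi2, thr$fst_hi, thr$fst_lo),
    sprintf("LND windows: %s = %d, %s = %d (shared %d; specific %d / %d)",
            sp[1], s$n_lnd[1], sp[2], s$n_lnd[2], s$n_lnd_shared,
            s$n_lnd_specific[1], s$n_lnd_specific[2]),
    sprintf("HIGD windows: %d", s$n_higd),
    sprintf("adaptive candidates: %s = %d, %s = %d",
            sp[1], s$n_adaptive[1], sp[2], s$n_adaptive[2]),
    sprintf("divergent candidates (LND both + HIGD): %d", s$n_divergent),
    sprintf("shared LND with bottom-tail FST: %d", s$n_shared_lnd_low_fst))
}

#' Spearman correlation of two window vectors
#'
#' Rank correlation with average ranks for ties, over pairwise-complete
#' windows.
#'
#' @param x,y numeric vectors of equal length.
#' @return Spearman's rho.
#' @export
correlate_windows <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs")
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Venn partition of variants across taxa
#'
#' A variant is "present" in a taxon when any of its samples carries a
#' non-reference allele.  Returns counts for every region of the Venn
#' partition of 2-4 taxa, keyed by membership pattern (e.g. `"110"` = first
#' two taxa only), plus percentages of the union.
#'
#' @param matrices named list (2-4 entries) of `genotype_matrix` objects,
#'   one per taxon, over a common site universe.
#' @return data.frame with columns `pattern`, `taxa`, `count`, `percent`.
#' @export
venn_partition <- function(matrices) {
  k <- length(matrices)
  if (k < 2L || k > 4L) stop("venn_partition supports 2-4 taxa")
  if (is.null(names(matrices)) || anyDuplicated(names(matrices)))
    stop("matrices must have unique taxon names")
  keys <- lapply(matrices, function(gm) {
    present <- rowSums(gm$geno > 0L, na.rm = TRUE) > 0L
    paste(gm$chrom, gm$pos, gm$ref, gm$alt, sep = ":")[present]
  })
  universe <- unique(unlist(keys))
  member <- vapply(keys, function(kk) universe %in% kk, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  all_patterns <- apply(expand.grid(rep(list(1:0), k))[, k:1, drop = FALSE],
                        1L, paste, collapse = "")
  all_patterns <- setdiff(all_patterns, strrep("0", k))
  counts <- table(factor(pattern, levels = all_patterns))
  data.frame(pattern = names(counts),
             taxa = vapply(names(counts), function(p) {
               paste(names(matrices)[strsplit(p, "")[[1]] == "1"],
                     collapse = "&")
             }, character(1)),
             count = as.integer(counts),
             percent = if (length(universe))
               100 * as.integer(counts) / length(universe) else
               rep(0, length(counts)),
             row.names = NULL)
}
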