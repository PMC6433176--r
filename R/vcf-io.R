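#' Read a multi-sample VCF
#'
#' Thin wrapper around [VariantAnnotation::readVcf()] that returns the raw
#' site-level records needed by the filtering step: positions, alleles, the
#' site-level mapping-quality annotation (`INFO/MQ`), per-sample read depths
#' (`FORMAT/DP`) and unparsed genotype strings.  Sites are returned in
#' coordinate order; missing calls (`./.`) are preserved; samples are never
#' dropped.
#'
#' @param path path to a VCF v4.x file (plain or bgzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` string restricting
#'   the returned sites.
#' @return an object of class `variant_sites`: a list with fields `chrom`,
#'   `pos`, `ref`, `alt` (list of alternate-allele vectors), `mq`, `dp`
#'   (sites x samples), `gt` (sites x samples genotype strings), `samples`,
#'   `chrom_lengths`.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  rr <- SummarizedExperiment::rowRanges(v)
  n <- length(rr)
  samples <- colnames(v)
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  gt <- matrix(as.character(gt), nrow = n, ncol = length(samples),
               dimnames = list(NULL, samples))
  dp <- VariantAnnotation::geno(v)$DP
  if (!is.null(dp)) {
    dp <- matrix(suppressWarnings(as.numeric(dp)), nrow = n,
                 ncol = length(samples), dimnames = list(NULL, samples))
  } else if (!is.null(VariantAnnotation::info(v)$DP)) {
    warning("per-sample DP absent; using site DP / n_samples")
    site_dp <- as.numeric(VariantAnnotation::info(v)$DP) /
      max(1L, length(samples))
    dp <- matrix(site_dp, nrow = n, ncol = length(samples),
                 dimnames = list(NULL, samples))
  }
  mq <- VariantAnnotation::info(v)$MQ
  mq <- if (is.null(mq)) rep(NA_real_, n) else as.numeric(mq)
  sites <- structure(
    list(chrom = as.character(GenomicRanges::seqnames(rr)),
         pos = GenomicRanges::start(rr),
         ref = as.character(VariantAnnotation::ref(v)),
         alt = lapply(VariantAnnotation::alt(v), as.character),
         mq = mq, dp = dp, gt = gt, samples = samples,
         chrom_lengths = clean_seqlengths(GenomeInfoDb::seqinfo(v))),
    class = "variant_sites")
  if (!is.null(region)) sites <- subset_region(sites, region)
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) sites <- vs_subset(sites, ord)
  sites
}

clean_seqlengths <- function(si) {
  sl <- GenomeInfoDb::seqlengths(si)
  if (all(is.na(sl))) NULL else sl[!is.na(sl)]
}

vs_subset <- function(vs, idx) {
  vs$chrom <- vs$chrom[idx]; vs$pos <- vs$pos[idx]
  vs$ref <- vs$ref[idx]; vs$alt <- vs$alt[idx]; vs$mq <- vs$mq[idx]
  vs$gt <- vs$gt[idx, , drop = FALSE]
  if (!is.null(vs$dp)) vs$dp <- vs$dp[idx, , drop = FALSE]
  vs
}

subset_region <- function(vs, region) {
  m <- regmatches(region,
                  regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m)) stop("malformed region: ", region)
  keep <- vs$chrom == m[2]
  if (nzchar(m[3]))
    keep <- keep & vs$pos >= as.integer(m[4]) & vs$pos <= as.integer(m[5])
  vs_subset(vs, which(keep))
}

#' @export
print.variant_sites <- function(x, ...) {
  cat(sprintf("variant_sites: %d records, %d samples\n",
              length(x$pos), length(x$samples)))
  invisible(x)
}

#' Number of variant records
#' @param vs a `variant_sites` object.
#' @return integer count.
#' @export
n_sites <- function(vs) length(vs$pos)

parse_gt <- function(gt) {
  # unphased or phased diploid ("0/1", "1|0"), haploid ("0"), missing (".")
  a <- strsplit(gt, "[/|]", fixed = FALSE)
  len <- lengths(a)
  if (length(unique(len[len > 0L])) > 1L)
    stop("mixed ploidy within one matrix")
  ploidy <- if (length(len)) max(len) else 2L
  flat <- suppressWarnings(as.integer(unlist(a)))
  dos <- matrix(flat, nrow = ploidy)
  dosage <- colSums(dos)                 # NA when any allele missing
  list(dosage = dosage, ploidy = as.integer(ploidy),
       alleles = dos)
}

#' Filter variants and build a genotype matrix
#'
#' Applies the study's variant filters: keep only biallelic SNPs with
#' site-level mapping quality strictly above `mq_min` (MQ > 20) and set to
#' missing any genotype whose per-sample read depth is not strictly above
#' `dp_min` (DP > 3).  Sites whose missing-call fraction then exceeds
#' `max_missing` are dropped.  INDELs and multiallelic records are removed,
#' never decomposed.
#'
#' @param vs a `variant_sites` object from [read_vcf()].
#' @param mq_min mapping-quality cutoff (strict `>`); default 20.
#' @param dp_min per-sample depth cutoff (strict `>`); default 3.
#' @param max_missing maximum tolerated per-site missing-call fraction after
#'   depth masking; default 0.2.
#' @param keep_indels if TRUE, biallelic INDELs passing the same filters are
#'   kept (used by the shared-variant Venn analysis); the default FALSE
#'   restricts to SNPs, the substrate of all window statistics.
#' @return a `genotype_matrix`; empty (with a warning) when nothing passes.
#' @export
filter_variants <- function(vs, mq_min = 20, dp_min = 3, max_missing = 0.2,
                            keep_indels = FALSE) {
  n <- length(vs$pos)
  nalt <- lengths(vs$alt)
  alt1 <- vapply(vs$alt, function(a) if (length(a)) a[1] else NA_character_,
                 character(1))
  is_snp <- nalt == 1L & nchar(vs$ref) == 1L & nchar(alt1) == 1L &
    vs$ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T")
  biallelic <- nalt == 1L & if (keep_indels) TRUE else is_snp
  mq_ok <- !is.na(vs$mq) & vs$mq > mq_min
  keep <- which(biallelic & mq_ok)
  if (!length(keep)) {
    warning("no variants pass the filters")
    return(genotype_matrix(character(0), integer(0), character(0),
                           character(0), matrix(integer(0), 0,
                                                length(vs$samples)),
                           vs$samples, 2L, vs$chrom_lengths))
  }
  gt <- vs$gt[keep, , drop = FALSE]
  pg <- parse_gt(gt)
  geno <- matrix(pg$dosage, nrow = length(keep),
                 dimnames = list(NULL, vs$samples))
  if (!is.null(vs$dp)) {
    low <- vs$dp[keep, , drop = FALSE] <= dp_min
    low[is.na(low)] <- TRUE
    geno[low] <- NA_integer_
  }
  miss_frac <- rowMeans(is.na(geno))
  ok <- miss_frac <= max_missing
  if (!any(ok)) {
    warning("no variants pass the filters")
    ok <- rep(FALSE, length(keep))
  }
  genotype_matrix(vs$chrom[keep][ok], vs$pos[keep][ok], vs$ref[keep][ok],
                  unlist(vs$alt[keep])[ok], geno[ok, , drop = FALSE],
                  vs$samples, pg$ploidy, vs$chrom_lengths)
}

dosage_to_gt <- function(d, ploidy) {
  if (ploidy == 1L) {
    out <- as.character(d)
    out[is.na(d)] <- "."
  } else {
    out <- c("0/0", "0/1", "1/1")[d + 1L]
    out[is.na(d)] <- "./."
  }
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' The writer populates `INFO/MQ` and `FORMAT/GT:DP` so that the filtering
#' path can be exercised on its own output, and declares contigs from
#' `chrom_lengths`.  Genotype fields round-trip bit-faithfully through
#' [read_vcf()] + [filter_variants()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param mq per-site MQ values (recycled); default 60.
#' @param dp per-sample depths, a sites x samples matrix or a scalar
#'   (recycled); default 20.
#' @return the path, invisibly.
#' @export
write_vcf <- function(gm, path, mq = 60, dp = 20) {
  n <- length(gm$pos)
  mq <- rep_len(mq, n)
  if (!is.matrix(dp)) dp <- matrix(dp, n, length(gm$samples))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divscan",
           if (!is.null(gm$chrom_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(gm$chrom_lengths),
                     as.integer(gm$chrom_lengths)),
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n > 0L) {
    gt <- matrix(dosage_to_gt(gm$geno, gm$ploidy), n)
    cells <- matrix(paste(gt, as.integer(dp), sep = ":"), n)
    body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS",
                  sprintf("MQ=%g", mq), "GT:DP",
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Dump a genotype matrix as TSV (debugging aid)
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(chrom = gm$chrom, pos = gm$pos, ref = gm$ref,
                   alt = gm$alt, gm$geno, check.names = FALSE)
  names(df)[-(1:4)] <- gm$samples
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
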