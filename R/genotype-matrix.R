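#' Construct a genotype matrix
#'
#' The central container of the package: biallelic calls for `n_sites` sites
#' by `n_samples` samples, stored as alternate-allele dosage (0..ploidy, `NA`
#' for a missing call).  Diploid genotypes are unphased; a dosage of 1 marks a
#' heterozygote.  Missing calls are representable and distinct from
#' homozygous-reference (dosage 0).
#'
#' @param chrom character vector of chromosome identifiers, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of reference / alternate alleles.
#' @param geno integer matrix, sites x samples, of alt-allele dosages
#'   (0..ploidy or `NA`).
#' @param samples character vector of sample identifiers (column order of
#'   `geno`).
#' @param ploidy 1 (haploid, e.g. chloroplast) or 2 (diploid nuclear).
#' @param chrom_lengths optional named numeric vector of chromosome lengths in
#'   bp; required for window tiling and per-bp denominators.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, geno, samples,
                            ploidy = 2L, chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  n_sites <- length(chrom)
  stopifnot(length(pos) == n_sites, length(ref) == n_sites,
            length(alt) == n_sites, ploidy %in% c(1L, 2L))
  if (n_sites == 0L) geno <- matrix(integer(0), 0L, length(samples))
  stopifnot(nrow(geno) == n_sites, ncol(geno) == length(samples))
  if (n_sites > 0L && any(pos < 1L)) stop("positions must be >= 1")
  rng <- suppressWarnings(range(geno, na.rm = TRUE))
  if (n_sites > 0L && is.finite(rng[1]) && (rng[1] < 0 || rng[2] > ploidy))
    stop("dosages must lie in 0..ploidy")
  if (!is.null(chrom_lengths) && is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, samples = as.character(samples),
                 ploidy = as.integer(ploidy),
                 chrom_lengths = chrom_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples, ploidy %d\n",
              length(x$pos), length(x$samples), x$ploidy))
  if (length(x$chrom)) {
    tab <- table(x$chrom)
    cat("  chromosomes:", paste(sprintf("%s (%d)", names(tab), tab),
                                collapse = ", "), "\n")
  }
  miss <- if (length(x$geno)) mean(is.na(x$geno)) else 0
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$pos), length(x$samples))

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm a `genotype_matrix`.
#' @param sites logical or integer index over sites.
#' @param samples logical/integer index or character vector of sample names.
#' @return a `genotype_matrix`.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_along(gm$pos)
  if (is.null(samples)) samples <- seq_along(gm$samples)
  if (is.character(samples)) {
    idx <- match(samples, gm$samples)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    samples <- idx
  }
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites],
                  gm$alt[sites], gm$geno[sites, samples, drop = FALSE],
                  gm$samples[samples], gm$ploidy, gm$chrom_lengths)
}

#' Read a population map
#'
#' A population map assigns every sample to a species and a geographic group
#' (for this study system: `southern`, `middle`, `northern`, or `hybrid`).
#' The file is a 3-column TSV `sample<TAB>species<TAB>group`; lines starting
#' with `#` are comments.
#'
#' @param path path to the TSV file.
#' @return a data.frame with columns `sample`, `species`, `group`, class
#'   `population_map`.
#' @export
read_population_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("sample", "species", "group"))
  population_map(df$sample, df$species, df$group)
}

#' Construct a population map in code
#'
#' @param sample,species,group parallel character vectors.
#' @return a `population_map` data.frame.
#' @export
population_map <- function(sample, species, group = species) {
  if (anyDuplicated(sample)) stop("duplicated sample in population map")
  structure(data.frame(sample = as.character(sample),
                       species = as.character(species),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("population_map", "data.frame"))
}

#' Write a population map to TSV
#' @param pm a `population_map`.
#' @param path output path.
#' @export
write_population_map <- function(pm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sample\tspecies\tgroup", con)
  utils::write.table(pm, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Samples belonging to a population
#'
#' Species-level populations are the union of their geographic groups; a
#' `group` argument restricts to one group.  Hybrids (group `hybrid`) form
#' their own population and are never silently merged into a species.
#'
#' @param pm a `population_map`.
#' @param species species label.
#' @param group optional group label.
#' @return character vector of sample names.
#' @export
pop_samples <- function(pm, species, group = NULL) {
  keep <- pm$species == species
  if (!is.null(group)) keep <- keep & pm$group == group
  out <- pm$sample[keep]
  if (!length(out)) stop("no samples for species '", species, "'",
                         if (!is.null(group)) paste0(" group '", group, "'"))
  out
}

#' Check that a population map covers a genotype matrix
#' @param gm a `genotype_matrix`.
#' @param pm a `population_map`.
#' @return invisibly TRUE; errors when a sample lacks an assignment.
#' @export
validate_population_map <- function(gm, pm) {
  missing <- setdiff(gm$samples, pm$sample)
  if (length(missing))
    stop("samples without population assignment: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Per-site allele counts in a population
#'
#' Missing calls are excluded, so `ref + alt = total` called alleles at every
#' site; a fully missing site yields `(0, 0, 0)`.
#'
#' @param gm a `genotype_matrix`.
#' @param population character vector of sample names (subset of
#'   `gm$samples`).
#' @return matrix with one row per site and columns `ref`, `alt`, `total`.
#' @export
allele_counts <- function(gm, population = gm$samples) {
  idx <- match(population, gm$samples)
  if (!length(idx)) stop("empty population")
  if (anyNA(idx)) stop("population contains unknown sample(s)")
  g <- gm$geno[, idx, drop = FALSE]
  called <- !is.na(g)
  total <- gm$ploidy * rowSums(called)
  alt <- rowSums(g, na.rm = TRUE)
  cbind(ref = total - alt, alt = alt, total = total)
}

#' Heterozygote counts per site in a population
#'
#' Only meaningful for diploid matrices; used by the Weir-Cockerham FST
#' variance components.
#'
#' @inheritParams allele_counts
#' @return matrix with columns `het` (heterozygous genotypes) and `n_called`
#'   (called genotypes).
#' @export
het_counts <- function(gm, population = gm$samples) {
  idx <- match(population, gm$samples)
  if (!length(idx)) stop("empty population")
  g <- gm$geno[, idx, drop = FALSE]
  cbind(het = rowSums(g == 1L, na.rm = TRUE) * (gm$ploidy == 2L),
        n_called = rowSums(!is.na(g)))
}

#' Split a diploid matrix into homozygous and full matrices
#'
#' Mirrors the construction of the phylogenetic SNP matrices: after
#' restricting to sites with no missing data, the *homozygous* matrix keeps
#' only sites at which every sample is homozygous, while the *full*
#' (heterozygous) matrix keeps all sites, homozygous and heterozygous alike.
#' The homozygous site set is therefore always a subset of the full one.
#'
#' @param gm a diploid `genotype_matrix`.
#' @return list with elements `hom` and `full`, both `genotype_matrix`.
#' @export
split_hom_het <- function(gm) {
  if (gm$ploidy != 2L) stop("hom/het split is undefined for haploid matrices")
  complete <- rowSums(is.na(gm$geno)) == 0L
  full <- gm_subset(gm, sites = complete)
  all_hom <- rowSums(full$geno == 1L) == 0L
  list(hom = gm_subset(full, sites = all_hom), full = full)
}
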