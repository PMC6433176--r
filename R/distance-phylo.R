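#' Pairwise genetic distances from a SNP matrix
#'
#' Two conventions, matching the homozygous/heterozygous matrix split used
#' for distance trees:
#' * `hom`: p-distance over sites homozygous in every sample (fraction of
#'   such sites at which two samples differ);
#' * `het`: allele-sharing distance over all sites, comparing unphased
#'   diploid genotypes as unordered allele pairs:
#'   `d = mean(|dosage_i - dosage_j| / 2)`.
#'
#' Requires a no-missing matrix (the matrices are built that way upstream);
#' haploid matrices use the plain p-distance in either mode.
#'
#' @param gm a `genotype_matrix` without missing calls.
#' @param mode `"hom"` or `"het"`.
#' @return symmetric matrix of distances (substitutions per site), class
#'   `dist`-compatible plain matrix with sample labels.
#' @export
pairwise_distance <- function(gm, mode = c("het", "hom")) {
  mode <- match.arg(mode)
  if (length(gm$samples) < 2L) stop("need at least 2 samples")
  if (anyNA(gm$geno))
    stop("matrix contains missing calls; restrict to complete sites first")
  g <- gm$geno
  if (gm$ploidy == 2L && mode == "hom") {
    keep <- rowSums(g == 1L) == 0L
    if (!any(keep)) stop("no all-homozygous sites")
    g <- g[keep, , drop = FALSE] / 2L     # 0/1 allele per sample
  }
  div <- if (gm$ploidy == 2L && mode == "het") 2 else 1
  ns <- ncol(g)
  d <- matrix(0, ns, ns, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      d[i, j] <- d[j, i] <- mean(abs(g[, i] - g[, j]) / div)
    }
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; the result is ultrametric and rooted, with
#' branch lengths equal to half the cophenetic distances.  Ties are broken
#' deterministically by label order.
#'
#' @param d symmetric distance matrix with labels.
#' @return an [ape] `phylo` tree (rooted).
#' @export
upgma <- function(d) {
  if (any(is.na(d))) stop("distance matrix contains NA")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]; the output is unrooted.
#' Negative branch lengths (possible on non-additive input) are clamped to
#' zero with the deficit transferred to the adjacent branch into the same
#' node, the usual practice.
#'
#' @param d symmetric distance matrix with labels (>= 3 taxa).
#' @return an [ape] `phylo` tree (unrooted).
#' @export
neighbor_joining <- function(d) {
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (nrow(d) < 3L) stop("neighbor joining needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    up <- which(tr$edge[, 2L] == parent)
    if (length(up)) tr$edge.length[up] <- tr$edge.length[up] + deficit
  }
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths at 6-decimal precision, terminating semicolon; labels with
#' reserved characters are handled by [ape::write.tree()] quoting.
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Site-resampling bootstrap support for a distance tree
#'
#' Resamples sites with replacement, rebuilds the tree with the same method,
#' and reports majority-rule clade support on the original tree.
#'
#' @param gm a no-missing `genotype_matrix`.
#' @param mode distance mode, see [pairwise_distance()].
#' @param method `"upgma"` or `"nj"`.
#' @param B bootstrap replicates (default 100).
#' @return list with `tree` (the original tree) and `support` (per-node
#'   counts out of `B`).
#' @export
bootstrap_tree <- function(gm, mode = "het", method = c("upgma", "nj"),
                           B = 100L) {
  method <- match.arg(method)
  build <- function(m) {
    d <- pairwise_distance(m, mode)
    if (method == "upgma") upgma(d) else neighbor_joining(d)
  }
  tree <- build(gm)
  reps <- lapply(seq_len(B), function(b) {
    idx <- sample.int(length(gm$pos), replace = TRUE)
    build(gm_subset(gm, sites = idx))
  })
  support <- ape::prop.clades(tree, reps, rooted = method == "upgma")
  list(tree = tree, support = support, B = B)
}

#' Write a labeled distance matrix as TSV
#' @param d symmetric labeled matrix.
#' @param path output path.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(sample = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
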