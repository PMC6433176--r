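#' Demographic configuration for the two-species simulator
#'
#' The default scenario structurally mirrors the study design this package
#' targets: two diploid species (16 + 16 sampled accessions) split from a
#' common ancestor on the order of 2N generations ago, each passing through a
#' bottleneck near the split, with recent secondary-contact migration, two F1
#' hybrids, 7 nuclear chromosomes and a short (~129 kb) non-recombining
#' haploid chloroplast.  Chromosome lengths default to a desk-scale 5 Mb.
#'
#' @param n_anc,n_sp1,n_sp2 diploid effective sizes.
#' @param t_split split time in generations.
#' @param bottleneck list per species: `list(time, size, duration)`
#'   (generations back; must fall inside the species branch, i.e.
#'   `time + duration <= t_split`), or `NULL` for none.
#' @param migration per-lineage per-generation migration rate during the
#'   secondary-contact epoch `[0, t_contact]`; 0 disables.
#' @param t_contact end of the secondary-contact epoch (generations back).
#' @param mu nuclear per-bp per-generation mutation rate (default 1e-8).
#' @param mu_cp chloroplast mutation rate (default `mu / 5`).
#' @param generation_time years per generation (default 1).
#' @param r per-bp recombination rate (sets sweep footprints; loci are
#'   simulated as independent non-recombining segments).
#' @param chrom_lengths named nuclear chromosome lengths (bp).
#' @param cp_length chloroplast length (bp, default 129000).
#' @param n_sample_sp1,n_sample_sp2 diploid samples per species.
#' @param n_hybrids number of F1 hybrids to synthesize (default 2).
#' @param locus_size length of the independently simulated non-recombining
#'   loci (default 100 kb, matching the analysis window).
#' @return a validated `demography_config` list.
#' @export
demography_config <- function(n_anc = 10000, n_sp1 = 10000, n_sp2 = 10000,
                              t_split = 20000,
                              bottleneck = list(
                                sp1 = list(time = 14000, size = 2000,
                                           duration = 4000),
                                sp2 = list(time = 14000, size = 2000,
                                           duration = 4000)),
                              migration = 1e-5, t_contact = 2000,
                              mu = 1e-8, mu_cp = mu / 5,
                              generation_time = 1, r = 1e-8,
                              chrom_lengths = stats::setNames(
                                rep(5e6, 7), paste0("chr", 1:7)),
                              cp_length = 129000,
                              n_sample_sp1 = 16, n_sample_sp2 = 16,
                              n_hybrids = 2, locus_size = 1e5) {
  cfg <- list(n_anc = n_anc, n_sp1 = n_sp1, n_sp2 = n_sp2,
              t_split = t_split, bottleneck = bottleneck,
              migration = migration, t_contact = t_contact,
              mu = mu, mu_cp = mu_cp, generation_time = generation_time,
              r = r, chrom_lengths = chrom_lengths, cp_length = cp_length,
              n_sample_sp1 = n_sample_sp1, n_sample_sp2 = n_sample_sp2,
              n_hybrids = n_hybrids, locus_size = locus_size)
  validate_demography(cfg)
  structure(cfg, class = "demography_config")
}

validate_demography <- function(cfg) {
  chk <- function(ok, what) if (!ok) stop("invalid demography: ", what,
                                          call. = FALSE)
  chk(all(c(cfg$n_anc, cfg$n_sp1, cfg$n_sp2) > 0), "population sizes must be > 0")
  chk(cfg$t_split >= 0, "t_split must be >= 0")
  chk(cfg$migration >= 0 && cfg$mu >= 0 && cfg$r >= 0, "rates must be >= 0")
  for (sp in names(cfg$bottleneck)) {
    b <- cfg$bottleneck[[sp]]
    if (is.null(b)) next
    chk(b$size > 0, paste0(sp, " bottleneck size must be > 0"))
    chk(b$time >= 0 && b$duration >= 0,
        paste0(sp, " bottleneck time/duration must be >= 0"))
    chk(b$time + b$duration <= cfg$t_split,
        paste0(sp, " bottleneck must end before t_split (time + duration <= t_split)"))
  }
  chk(cfg$t_contact <= cfg$t_split, "t_contact must be <= t_split")
  chk(!is.null(names(cfg$chrom_lengths)), "chrom_lengths must be named")
  invisible(TRUE)
}

#' Sweep configuration
#'
#' Describes a completed hard sweep imposed on the neutral realization of
#' one species.  The physical footprint scale is
#' `s / (r * log(2 N s))` (the classic hitchhiking length), and the
#' probability that a lineage at distance `d` escapes the sweep is
#' `1 - exp(-d / footprint)`.  Diversity recovery since fixation is
#' approximated by damping the replacement probability by
#' `exp(-fixation_time / (2N))`.
#'
#' @param chrom chromosome name.
#' @param position sweep center (bp).
#' @param s selection coefficient (> 0).
#' @param fixation_time generations since fixation (default 0).
#' @param species `"sp1"` or `"sp2"`.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(chrom, position, s = 0.05, fixation_time = 0,
                         species = "sp1") {
  if (s <= 0) stop("selection coefficient must be > 0")
  structure(list(chrom = chrom, position = position, s = s,
                 fixation_time = fixation_time, species = species),
            class = "sweep_config")
}

# Piecewise-constant epochs (backwards in time) for the structured
# coalescent.  Returns breakpoints and a parameter lookup per epoch.
build_epochs <- function(cfg, scale = 1) {
  breaks <- sort(unique(c(0, cfg$t_contact,
                          unlist(lapply(cfg$bottleneck, function(b)
                            if (is.null(b)) NULL else c(b$time, b$time + b$duration))),
                          cfg$t_split, Inf)))
  size_at <- function(sp, t) {
    b <- cfg$bottleneck[[sp]]
    base <- if (sp == "sp1") cfg$n_sp1 else cfg$n_sp2
    if (!is.null(b) && t >= b$time && t < b$time + b$duration) b$size else base
  }
  lapply(seq_len(length(breaks) - 1L), function(i) {
    t0 <- breaks[i]
    list(t0 = t0, t1 = breaks[i + 1L],
         merged = t0 >= cfg$t_split,
         N1 = scale * if (t0 >= cfg$t_split) cfg$n_anc else size_at("sp1", t0),
         N2 = scale * size_at("sp2", t0),
         m = if (t0 < cfg$t_contact) cfg$migration else 0)
  })
}

# Structured coalescent for one non-recombining locus: k1/k2 sampled
# lineages in demes 1/2, two demes with migration that merge at t_split.
# Returns parent pointers and node times (leaves 1..k, internals appended).
sim_genealogy <- function(k1, k2, epochs) {
  n <- k1 + k2
  parent <- integer(2L * n - 1L)
  time <- numeric(2L * n - 1L)
  active <- seq_len(n)
  deme <- c(rep(1L, k1), rep(2L, k2))
  nxt <- n + 1L
  t <- 0
  ei <- 1L
  while (length(active) > 1L) {
    ep <- epochs[[ei]]
    if (ep$merged) deme[seq_along(active)] <- 1L
    k_1 <- sum(deme[seq_along(active)] == 1L)
    k_2 <- length(active) - k_1
    r_c1 <- k_1 * (k_1 - 1) / 2 / (2 * ep$N1)
    r_c2 <- if (ep$merged) 0 else k_2 * (k_2 - 1) / 2 / (2 * ep$N2)
    r_m <- if (ep$merged) 0 else ep$m * length(active)
    tot <- r_c1 + r_c2 + r_m
    if (tot <= 0) { t <- ep$t1; ei <- ei + 1L; next }
    dt <- stats::rexp(1L, tot)
    if (t + dt >= ep$t1) { t <- ep$t1; ei <- ei + 1L; next }
    t <- t + dt
    u <- stats::runif(1L) * tot
    if (u < r_c1 + r_c2) {
      d <- if (u < r_c1) 1L else 2L
      in_d <- which(deme[seq_along(active)] == d)
      pick <- sample(in_d, 2L)
      a <- active[pick[1L]]; b <- active[pick[2L]]
      parent[a] <- parent[b] <- nxt
      time[nxt] <- t
      active <- active[-pick]
      deme <- deme[-pick]
      active <- c(active, nxt)
      deme <- c(deme, d)
      nxt <- nxt + 1L
    } else {
      pick <- sample(length(active), 1L)
      deme[pick] <- 3L - deme[pick]
    }
  }
  list(parent = parent, time = time, n = n, root = nxt - 1L)
}

# Drop mutations on a genealogy: infinite-sites on L bp at rate mu.
# Returns haplotypes (n x S matrix of 0/1) and sorted positions in 1..L.
drop_mutations <- function(gen, L, mu) {
  nn <- gen$root
  len <- numeric(nn)
  has_parent <- gen$parent[seq_len(nn)] > 0L
  len[has_parent] <- gen$time[gen$parent[seq_len(nn)][has_parent]] -
    gen$time[seq_len(nn)][has_parent]
  total <- sum(len)
  n_mut <- stats::rpois(1L, mu * L * total)
  n_mut <- min(n_mut, L)                  # infinite-sites on a finite grid
  if (n_mut == 0L)
    return(list(haps = matrix(0L, gen$n, 0L), pos = integer(0)))
  edge_of <- sample.int(nn, n_mut, replace = TRUE, prob = len)
  pos <- sort(sample.int(L, n_mut))
  # leaf sets below every node, in coalescence (time) order
  leafset <- vector("list", nn)
  for (v in seq_len(gen$n)) leafset[[v]] <- v
  for (v in (gen$n + 1L):nn) {
    kids <- which(gen$parent[seq_len(nn)] == v)
    leafset[[v]] <- unlist(leafset[kids])
  }
  haps <- matrix(0L, gen$n, n_mut)
  for (m in seq_len(n_mut)) haps[leafset[[edge_of[m]]], m] <- 1L
  list(haps = haps, pos = pos)
}

apply_sweep_haps <- function(haps, pos, sweep, cfg, hap_idx) {
  N <- if (sweep$species == "sp1") cfg$n_sp1 else cfg$n_sp2
  footprint <- sweep$s / (cfg$r * log(2 * N * sweep$s))
  d <- abs(pos - sweep$position)
  p_replace <- exp(-d / footprint) * exp(-sweep$fixation_time / (2 * N))
  b <- hap_idx[1L]
  for (h in hap_idx[-1L]) {
    hit <- stats::runif(length(pos)) < p_replace
    haps[h, hit] <- haps[b, hit]
  }
  haps
}

#' Simulate a two-species divergence dataset
#'
#' Coalescent realization per independent non-recombining locus (default
#' 100 kb) on every nuclear chromosome, a single-locus haploid chloroplast
#' with effective size N/2 and reduced mutation rate, optional post-hoc hard
#' sweeps, and F1 hybrids synthesized from the parental genotypes.
#' Identical seeds give identical output.
#'
#' @param cfg a [demography_config()].
#' @param sweeps list of [sweep_config()] objects.
#' @param seed integer seed driving all randomness.
#' @return list with `nuclear` and `chloroplast` `genotype_matrix` objects
#'   (nuclear includes hybrids when requested), `popmap`
#'   (a [population_map()]), and `truth` (a `sim_truth` record).
#' @export
simulate_divergence <- function(cfg = demography_config(), sweeps = list(),
                                seed = 1L) {
  validate_demography(cfg)
  set.seed(seed)
  k1 <- 2L * cfg$n_sample_sp1
  k2 <- 2L * cfg$n_sample_sp2
  epochs <- build_epochs(cfg)
  chroms <- names(cfg$chrom_lengths)
  bases <- c("A", "C", "G", "T")
  all_chrom <- all_pos <- all_ref <- all_alt <- list()
  geno_chunks <- list()
  for (ch in chroms) {
    len <- cfg$chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = cfg$locus_size)
    hap_list <- list(); pos_list <- list()
    for (st in starts) {
      lsize <- min(cfg$locus_size, len - st)
      gen <- sim_genealogy(k1, k2, epochs)
      mut <- drop_mutations(gen, lsize, cfg$mu)
      hap_list[[length(hap_list) + 1L]] <- mut$haps
      pos_list[[length(pos_list) + 1L]] <- mut$pos + st
    }
    haps <- do.call(cbind, hap_list)
    pos <- unlist(pos_list)
    for (sw in sweeps) {
      if (sw$chrom != ch) next
      idx <- if (sw$species == "sp1") seq_len(k1) else k1 + seq_len(k2)
      haps <- apply_sweep_haps(haps, pos, sw, cfg, idx)
    }
    # drop sites monomorphic after the sweep transformation
    seg <- colSums(haps) > 0L & colSums(haps) < nrow(haps)
    haps <- haps[, seg, drop = FALSE]
    pos <- pos[seg]
    dos <- haps[seq(1, k1 + k2, by = 2), , drop = FALSE] +
      haps[seq(2, k1 + k2, by = 2), , drop = FALSE]
    ref <- bases[sample.int(4L, length(pos), replace = TRUE)]
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    all_chrom[[ch]] <- rep(ch, length(pos))
    all_pos[[ch]] <- pos; all_ref[[ch]] <- ref; all_alt[[ch]] <- alt
    geno_chunks[[ch]] <- t(dos)
  }
  sp1 <- sprintf("sp1_%02d", seq_len(cfg$n_sample_sp1))
  sp2 <- sprintf("sp2_%02d", seq_len(cfg$n_sample_sp2))
  samples <- c(sp1, sp2)
  nuclear <- genotype_matrix(unlist(all_chrom), unlist(all_pos),
                             unlist(all_ref), unlist(all_alt),
                             do.call(rbind, geno_chunks), samples,
                             ploidy = 2L, chrom_lengths = cfg$chrom_lengths)
  popmap <- default_popmap(cfg)
  if (cfg$n_hybrids > 0L) {
    hyb <- make_hybrids(nuclear, sp1, sp2, cfg$n_hybrids)
    nuclear$geno <- cbind(nuclear$geno, hyb$geno)
    nuclear$samples <- c(nuclear$samples, hyb$samples)
  }
  chloroplast <- sim_chloroplast(cfg, popmap)
  truth <- structure(list(config = unclass(cfg), sweeps = lapply(sweeps, unclass),
                          seed = seed,
                          n_variants = list(
                            nuclear = length(nuclear$pos),
                            chloroplast = length(chloroplast$pos))),
                     class = "sim_truth")
  list(nuclear = nuclear, chloroplast = chloroplast, popmap = popmap,
       truth = truth)
}

default_popmap <- function(cfg) {
  grp <- function(n, labels, sizes) rep(labels, sizes)[seq_len(n)]
  n1 <- cfg$n_sample_sp1; n2 <- cfg$n_sample_sp2
  population_map(
    sample = c(sprintf("sp1_%02d", seq_len(n1)),
               sprintf("sp2_%02d", seq_len(n2)),
               if (cfg$n_hybrids > 0) sprintf("hyb_%02d", seq_len(cfg$n_hybrids))),
    species = c(rep("sp1", n1), rep("sp2", n2),
                rep("hybrid", cfg$n_hybrids)),
    group = c(grp(n1, c("southern", "northern"),
                  c(ceiling(n1 / 2), floor(n1 / 2))),
              grp(n2, c("southern", "middle", "northern"),
                  c(ceiling(n2 / 3), floor(n2 / 3),
                    n2 - ceiling(n2 / 3) - floor(n2 / 3))),
              rep("hybrid", cfg$n_hybrids)))
}

sim_chloroplast <- function(cfg, popmap) {
  # haploid, uniparentally inherited: one lineage per individual, Ne = N/2
  cp_cfg <- cfg
  cp_cfg$n_anc <- cfg$n_anc / 2
  cp_cfg$n_sp1 <- cfg$n_sp1 / 2
  cp_cfg$n_sp2 <- cfg$n_sp2 / 2
  if (!is.null(cp_cfg$bottleneck)) {
    for (sp in names(cp_cfg$bottleneck))
      if (!is.null(cp_cfg$bottleneck[[sp]]))
        cp_cfg$bottleneck[[sp]]$size <- cp_cfg$bottleneck[[sp]]$size / 2
  }
  epochs <- build_epochs(cp_cfg)
  gen <- sim_genealogy(cfg$n_sample_sp1, cfg$n_sample_sp2, epochs)
  mut <- drop_mutations(gen, cfg$cp_length, cfg$mu_cp)
  haps <- mut$haps
  samples <- popmap$sample
  if (cfg$n_hybrids > 0L) {
    # each hybrid inherits its chloroplast from one random parental accession
    donors <- sample(nrow(haps), cfg$n_hybrids, replace = TRUE)
    haps <- rbind(haps, haps[donors, , drop = FALSE])
  }
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, length(mut$pos), replace = TRUE)]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  genotype_matrix(rep("chloroplast", length(mut$pos)), mut$pos, ref, alt,
                  t(haps), samples, ploidy = 1L,
                  chrom_lengths = c(chloroplast = cfg$cp_length))
}

#' Synthesize F1 hybrids from two parental species
#'
#' Each hybrid draws one random parent per species and one gamete per
#' parent.  Parental genotypes are unphased, so a heterozygous site
#' transmits either allele with probability 1/2 independently across sites;
#' homozygous sites transmit deterministically — hence every hybrid is
#' heterozygous at every parental fixed-difference site.
#'
#' @param gm diploid `genotype_matrix` containing both parental species.
#' @param parents1,parents2 sample names of the two species.
#' @param n number of hybrids (>= 1).
#' @param prefix sample-name prefix for the hybrids.
#' @return a `genotype_matrix` holding only the hybrid samples (same sites
#'   as `gm`).
#' @export
make_hybrids <- function(gm, parents1, parents2, n, prefix = "hyb") {
  if (n < 1L) stop("n must be >= 1")
  if (!length(parents1) || !length(parents2))
    stop("both parental species must be present")
  gamete <- function(parent) {
    g <- gm$geno[, match(parent, gm$samples)]
    out <- integer(length(g))
    out[g == 2L] <- 1L
    het <- which(g == 1L)
    out[het] <- stats::rbinom(length(het), 1L, 0.5)
    out[is.na(g)] <- NA_integer_
    out
  }
  geno <- vapply(seq_len(n), function(i) {
    gamete(sample(parents1, 1L)) + gamete(sample(parents2, 1L))
  }, integer(length(gm$pos)))
  if (length(gm$pos) == 0L) geno <- matrix(integer(0), 0L, n)
  genotype_matrix(gm$chrom, gm$pos, gm$ref, gm$alt, geno,
                  sprintf("%s_%02d", prefix, seq_len(n)),
                  ploidy = 2L, chrom_lengths = gm$chrom_lengths)
}

#' Write a simulation truth record as JSON
#' @param truth a `sim_truth` from [simulate_divergence()].
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  x <- unclass(truth)
  # named vectors lose names as JSON arrays; store as objects
  x$config$chrom_lengths <- as.list(x$config$chrom_lengths)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a demography scenario from JSON
#'
#' Keys mirror the arguments of [demography_config()]; absent keys take the
#' defaults.
#'
#' @param path JSON file.
#' @return a `demography_config`.
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$chrom_lengths))
    raw$chrom_lengths <- unlist(raw$chrom_lengths)
  if (!is.null(raw$bottleneck))
    raw$bottleneck <- lapply(raw$bottleneck, as.list)
  do.call(demography_config, raw)
}
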