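#' Run configuration for the end-to-end pipeline
#'
#' Defaults reproduce the analysis settings of the study design this package
#' implements: 100-kb non-overlapping windows, 5% outlier tails, 2,000 scan
#' bins per chromosome with a CLR > 20 sweep call, and MQ > 20 / DP > 3
#' variant filters.
#'
#' @param vcf path to a multi-sample VCF (alternative to `scenario`).
#' @param popmap path to a population-map TSV (required with `vcf`).
#' @param scenario a [demography_config()] or path to a scenario JSON; when
#'   given, input data are simulated.
#' @param sweeps list of [sweep_config()] for simulated runs.
#' @param window_size window size in bp.
#' @param quantile outlier tail mass.
#' @param n_bins sweep-scan bins per chromosome.
#' @param clr_threshold sweep call threshold.
#' @param mq_min,dp_min,max_missing variant filters.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; all stage randomness derives from it.
#' @return a `run_config` list.
#' @export
run_config <- function(vcf = NULL, popmap = NULL, scenario = NULL,
                       sweeps = list(), window_size = 1e5, quantile = 0.05,
                       n_bins = 2000L, clr_threshold = 20, mq_min = 20,
                       dp_min = 3, max_missing = 0.2, out_dir = "divscan_out",
                       seed = 1L) {
  if (is.null(scenario) && (is.null(vcf) || is.null(popmap)))
    stop("either a scenario or both vcf and popmap must be given",
         call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]   # analytic settings only
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

provenance <- function(cfg, stage) {
  sprintf("divscan %s | stage=%s | seed=%d | config=%s",
          as.character(utils::packageVersion("divscan")), stage, cfg$seed,
          config_hash(unclass(cfg)))
}

#' Run the full divergence-analysis pipeline
#'
#' filter -> windows -> divergence statistics -> outlier classification ->
#' per-species sweep scans -> distance trees -> summary.  Every output file
#' carries a provenance header (package version, seed, config hash); a rerun
#' with identical config and inputs is byte-identical.
#'
#' @param cfg a [run_config()].
#' @return the output directory, invisibly; files:
#'   `windows.tsv`, `outliers.tsv`, `sweeps_<species>.tsv`,
#'   `upgma_het.nwk`, `nj_hom.nwk`, `distances_het.tsv`, `summary.txt`,
#'   plus `simulated.vcf` / `popmap.tsv` / `truth.json` for simulated runs.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage <- "input"
  tryCatch({
    if (!is.null(cfg$scenario)) {
      scen <- if (is.character(cfg$scenario)) read_scenario(cfg$scenario)
              else cfg$scenario
      sim <- simulate_divergence(scen, cfg$sweeps, seed = cfg$seed)
      vcf_path <- file.path(cfg$out_dir, "simulated.vcf")
      write_vcf(sim$nuclear, vcf_path)
      write_population_map(sim$popmap, file.path(cfg$out_dir, "popmap.tsv"))
      write_sim_truth(sim$truth, file.path(cfg$out_dir, "truth.json"))
      vs <- read_vcf(vcf_path)
      pm <- sim$popmap
    } else {
      if (!file.exists(cfg$popmap)) stop("population map not found: ",
                                         cfg$popmap)
      vs <- read_vcf(cfg$vcf)
      pm <- read_population_map(cfg$popmap)
    }
    stage <- "filter"
    gm <- filter_variants(vs, cfg$mq_min, cfg$dp_min, cfg$max_missing)
    validate_population_map(gm, pm)
    species <- setdiff(unique(pm$species), "hybrid")[1:2]
    pops <- stats::setNames(lapply(species, pop_samples, pm = pm), species)
    stage <- "windows"
    ws <- window_stats(gm, pops, size = cfg$window_size)
    write_window_stats(ws, file.path(cfg$out_dir, "windows.tsv"),
                       provenance(cfg, stage))
    stage <- "scan-outliers"
    oc <- classify_outliers(ws, species, cfg$quantile)
    write_window_stats(oc, file.path(cfg$out_dir, "outliers.tsv"),
                       provenance(cfg, stage))
    stage <- "scan-sweeps"
    scans <- lapply(species, function(sp) {
      sc <- sweep_scan(gm, pops[[sp]], cfg$n_bins, cfg$clr_threshold)
      write_sweep_scan(sc, file.path(cfg$out_dir,
                                     paste0("sweeps_", sp, ".tsv")),
                       provenance(cfg, stage))
      sc
    })
    names(scans) <- species
    stage <- "tree"
    hh <- split_hom_het(gm)
    d_het <- pairwise_distance(hh$full, "het")
    write_distance_tsv(d_het, file.path(cfg$out_dir, "distances_het.tsv"))
    write_newick(upgma(d_het), file.path(cfg$out_dir, "upgma_het.nwk"))
    if (length(hh$hom$pos) > 0L && length(hh$hom$samples) >= 3L)
      write_newick(neighbor_joining(pairwise_distance(hh$hom, "hom")),
                   file.path(cfg$out_dir, "nj_hom.nwk"))
    stage <- "summary"
    lines <- c(paste0("# ", provenance(cfg, stage)),
               sprintf("filters: MQ > %g, DP > %g, max missing %.2f",
                       cfg$mq_min, cfg$dp_min, cfg$max_missing),
               sprintf("window size: %d bp; outlier tail: %.3f; bins: %d; CLR threshold: %g",
                       as.integer(cfg$window_size), cfg$quantile,
                       as.integer(cfg$n_bins), cfg$clr_threshold),
               sprintf("sites retained: %d; samples: %d", length(gm$pos),
                       length(gm$samples)),
               outlier_summary(oc),
               vapply(species, function(sp) {
                 sprintf("sweep bins CLR > %g in %s: %d of %d", cfg$clr_threshold,
                         sp, sum(scans[[sp]]$is_sweep),
                         sum(!is.na(scans[[sp]]$clr)))
               }, character(1)))
    writeLines(lines, file.path(cfg$out_dir, "summary.txt"))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(cfg$out_dir)
}
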