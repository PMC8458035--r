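ref_labels <- c(bulk_called = "bulkCalled", population_full = "popFull",
                population_utr_filtered = "popUTR",
                array_subset = "arraySubset", sites_only = "sitesOnly")
demux_labels <- c(genotype_aware = "gtAware", genotype_free = "gtFree")

#' Benchmark scenario configuration
#'
#' One scenario = one synthetic pooled dataset (with optional doublet and
#' debris perturbations) demultiplexed under one genotype-reference
#' strategy and one demultiplexer. Scenario names follow the
#' "genotypeMethod_demultiplexingMethod" convention.
#'
#' Dataset defaults are the study conditions of the benchmark, scaled to
#' desk size: 3 donors x 120 cells over 1,000 germline SNPs, somatic SNVs
#' at TMB 20/Mb over 10 Mb of covered transcribed sequence, CNV
#' allele-fraction skew on 20% of het sites, mean 1 read per site per
#' cell, error rate 0.001, matched bulk at 100x.
#'
#' @param donors Number of donors K.
#' @param cells_per_donor Cells per donor (recycled to length K).
#' @param n_snps Germline panel size.
#' @param utr_fraction Fraction of panel SNPs tagged 3' UTR.
#' @param tmb_per_mb Somatic mutations per megabase (0 disables).
#' @param covered_mb Covered megabases for the somatic model.
#' @param cnv_fraction Fraction of het sites receiving CNV skew per donor.
#' @param mean_site_depth,depth_dispersion,error_rate Cell-count model;
#'   see [cell_sim_config()].
#' @param bulk_mean_depth Matched-bulk depth for `bulk_called` references.
#' @param doublet_fraction Target doublet fraction among final barcodes.
#' @param debris_fraction Fraction of barcodes turned into ambient debris.
#' @param reference One of `"bulk_called"`, `"population_full"`,
#'   `"population_utr_filtered"`, `"array_subset"`, `"sites_only"`.
#' @param demultiplexer `"genotype_aware"` (needs donor genotypes, i.e. a
#'   `bulk_called` or `array_subset` reference) or `"genotype_free"`.
#' @param array_fraction Panel fraction kept by the emulated SNP array.
#' @param doublet_prior,assign_threshold Demultiplexer decision rule; a
#'   `NULL` doublet prior defaults to the designed doublet fraction (0.05
#'   when no doublets are simulated).
#' @param seed Master seed; all stage streams derive from it.
#' @param name Scenario name override.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(donors = 3L, cells_per_donor = 120L,
                            n_snps = 1000L, utr_fraction = 0.25,
                            tmb_per_mb = 20, covered_mb = 10,
                            cnv_fraction = 0.2, mean_site_depth = 1.0,
                            depth_dispersion = 0.3, error_rate = 0.001,
                            bulk_mean_depth = 100,
                            doublet_fraction = 0, debris_fraction = 0,
                            reference = "bulk_called",
                            demultiplexer = "genotype_aware",
                            array_fraction = 0.5, doublet_prior = NULL,
                            assign_threshold = 0.9, seed = 1L,
                            name = NULL) {
  reference <- match.arg(reference, names(ref_labels))
  demultiplexer <- match.arg(demultiplexer, names(demux_labels))
  if (demultiplexer == "genotype_aware" &&
      !reference %in% c("bulk_called", "array_subset"))
    stop("genotype-aware demultiplexing needs donor genotypes; use a ",
         "'bulk_called' or 'array_subset' reference")
  cells_per_donor <- rep_len(as.integer(cells_per_donor), donors)
  if (is.null(name))
    name <- paste0(ref_labels[[reference]], "_",
                   demux_labels[[demultiplexer]])
  cfg <- list(donors = as.integer(donors), cells_per_donor = cells_per_donor,
              n_snps = as.integer(n_snps), utr_fraction = utr_fraction,
              tmb_per_mb = tmb_per_mb, covered_mb = covered_mb,
              cnv_fraction = cnv_fraction,
              mean_site_depth = mean_site_depth,
              depth_dispersion = depth_dispersion, error_rate = error_rate,
              bulk_mean_depth = bulk_mean_depth,
              doublet_fraction = doublet_fraction,
              debris_fraction = debris_fraction, reference = reference,
              demultiplexer = demultiplexer,
              array_fraction = array_fraction,
              doublet_prior = doublet_prior,
              assign_threshold = assign_threshold,
              seed = as.integer(seed), name = name)
  class(cfg) <- "scenario_config"
  cfg
}

#' Run one benchmark scenario end to end
#'
#' Stages: germline panel and genotypes, somatic SNVs, CNV skew, per-cell
#' counts, doublet simulation, debris redistribution, reference
#' construction, demultiplexing, evaluation. Every stage draws from a
#' substream derived from the master seed and the scenario name, so runs
#' are bit-reproducible and independent across scenarios. When `out_dir`
#' is given, counts, truth, reference, assignments, metrics and the
#' resolved config (YAML) are written there.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional output directory.
#' @param verbose Print one line per stage?
#' @return List of class `scenario_run`: `config`, `report`
#'   ([eval_report()]), `metrics` (long data frame), `truth`, `result`,
#'   `n_doublets`, `model` (genotype-free only).
#' @export
run_scenario <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  # stage substreams derive from the master seed and the stage label only:
  # scenarios sharing a seed and dataset spec therefore demultiplex the
  # *same* pooled data, as a method comparison requires
  sseed <- function(stage) derive_seed(config$seed, stage)
  say <- function(...) if (verbose) message("[", config$name, "] ", ...)

  panel <- generate_snp_panel(config$n_snps, utr_fraction = config$utr_fraction,
                              seed = sseed("panel"))
  geno <- generate_donor_genotypes(panel, config$donors, seed = sseed("geno"))
  germline_panel <- panel
  germline_geno <- geno
  if (config$tmb_per_mb > 0) {
    ext <- apply_somatic_snvs(geno, panel, config$tmb_per_mb,
                              config$covered_mb, seed = sseed("somatic"))
    geno <- ext$genotypes; panel <- ext$panel
  }
  if (config$cnv_fraction > 0)
    geno <- apply_cnv_allele_skew(geno, config$cnv_fraction,
                                  seed = sseed("cnv"))
  say("panel: ", nrow(panel), " sites (",
      sum(panel$origin == "somatic"), " somatic)")

  sim <- simulate_cell_counts(geno, panel, cell_sim_config(
    config$cells_per_donor, config$mean_site_depth,
    config$depth_dispersion, config$error_rate, seed = sseed("cells")))
  counts <- sim$counts; truth <- sim$truth

  n_doublets <- 0L
  if (config$doublet_fraction > 0) {
    db <- simulate_doublets(counts, truth, config$doublet_fraction,
                            seed = sseed("doublets"))
    counts <- db$counts; truth <- db$truth; n_doublets <- nrow(db$plan)
    say("doublets: ", n_doublets, " merges, ", nrow(counts$AD),
        " barcodes remain")
  }
  if (config$debris_fraction > 0) {
    de <- simulate_debris(counts, truth, config$debris_fraction,
                          seed = sseed("debris"))
    counts <- de$counts; truth <- de$truth
    say("debris: ", nrow(de$plan), " barcodes redistributed")
  }

  # reference construction (germline panel; bulk sees the extended panel,
  # including somatic sites, as real bulk sequencing would)
  ref <- switch(config$reference,
    bulk_called = {
      bulk <- simulate_bulk_counts(geno, panel, config$bulk_mean_depth,
                                   config$error_rate, seed = sseed("bulk"))
      list(panel = panel, genotypes = call_genotypes_from_bulk(bulk))
    },
    population_full = list(panel = germline_panel, genotypes = NULL),
    population_utr_filtered = {
      p <- filter_panel_by_region(germline_panel, "three_prime_utr")
      list(panel = p, genotypes = NULL)
    },
    array_subset = {
      arr <- sample_array_panel(germline_panel, config$array_fraction,
                                seed = sseed("array"))
      bulk <- simulate_bulk_counts(geno, panel, config$bulk_mean_depth,
                                   config$error_rate, seed = sseed("bulk"))
      called <- call_genotypes_from_bulk(bulk)
      inter <- intersect_panels(panel, arr)
      list(panel = inter,
           genotypes = subset_genotypes(called, attr(inter, "site_index")))
    },
    sites_only = list(panel = sites_with_coverage(counts, panel),
                      genotypes = NULL))
  say("reference (", config$reference, "): ", nrow(ref$panel), " sites")

  delta <- config$doublet_prior
  if (is.null(delta))
    delta <- if (config$doublet_fraction > 0) config$doublet_fraction
             else 0.05
  dcfg <- demux_config(error_rate = config$error_rate,
                       doublet_prior = delta,
                       assign_threshold = config$assign_threshold,
                       K = config$donors, seed = sseed("demux"))
  model <- NULL
  if (config$demultiplexer == "genotype_aware") {
    if (is.null(ref$genotypes))
      stop("reference strategy '", config$reference,
           "' provides no genotypes")
    result <- demux_with_genotypes(counts, panel, ref$genotypes,
                                   ref_panel = ref$panel, config = dcfg)
    report <- eval_report(result, truth, match_labels = FALSE)
  } else {
    # restrict scoring to the reference's sites (match by site key; the
    # reference may derive from the germline panel while the count matrix
    # spans the somatic-extended one)
    sites <- ref$panel
    idx <- match(panel_key(sites), panel_key(panel))
    attr(sites, "site_index") <- idx[!is.na(idx)]
    fit <- demux_genotype_free(counts, sites, dcfg)
    result <- fit$result; model <- fit$model
    report <- eval_report(result, truth, match_labels = TRUE)
  }
  metrics <- cbind(scenario = config$name,
                   doublet_fraction = config$doublet_fraction,
                   debris_fraction = config$debris_fraction,
                   report$metrics, stringsAsFactors = FALSE)
  say("mean recall ", round(mean(metrics$recall, na.rm = TRUE), 4),
      ", mean precision ", round(mean(metrics$precision, na.rm = TRUE), 4))

  run <- structure(list(config = config, report = report,
                        metrics = metrics, truth = truth,
                        result = report$result, counts = counts,
                        panel = panel, n_doublets = n_doublets,
                        model = model),
                   class = "scenario_run")
  if (!is.null(out_dir)) {
    dir <- file.path(out_dir, config$name)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_allele_counts(counts, panel, file.path(dir, "counts"))
    write_truth(truth, file.path(dir, "truth.tsv"))
    write_sites_vcf(ref$panel, file.path(dir, "reference.vcf"),
                    ref$genotypes)
    write_assignments(report$result, file.path(dir, "assignments.tsv"))
    utils::write.table(metrics, file.path(dir, "metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(report$confusion),
                       file.path(dir, "confusion.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  run
}

#' Run a grid of benchmark scenarios
#'
#' @param configs List of [scenario_config()] objects with unique names.
#' @param out_dir Optional output directory (one subdirectory per
#'   scenario).
#' @param verbose Print stage logs?
#' @return Long-format metrics data frame (scenario, doublet and debris
#'   levels, per-sample precision/recall), sorted by scenario then
#'   sample so the table is independent of execution order; the
#'   individual runs are attached as attribute `"runs"`.
#' @export
run_grid <- function(configs, out_dir = NULL, verbose = FALSE) {
  stopifnot(length(configs) >= 1)
  nm <- vapply(configs, function(cf) cf$name, "")
  if (anyDuplicated(nm))
    stop("duplicate scenario names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  runs <- lapply(configs, run_scenario, out_dir = out_dir,
                 verbose = verbose)
  metrics <- do.call(rbind, lapply(runs, `[[`, "metrics"))
  metrics <- metrics[order(metrics$scenario, metrics$sample), ,
                     drop = FALSE]
  rownames(metrics) <- NULL
  attr(metrics, "runs") <- stats::setNames(runs, nm)
  metrics
}
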