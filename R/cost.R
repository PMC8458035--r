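#' Cost assumptions for multiplexed experimental designs
#'
#' Defaults follow a standard droplet scRNA-seq costing: $2,000 library
#' preparation per library (or per multiplexed set prepared as one
#' library), $1,500 per 400 million reads of sequencing with a 30%
#' overhead for unaligned reads and adapters, ~20,000 reads per cell, and
#' 4,000 desired cells per sample after demultiplexing. The droplet
#' doublet rate is modelled as linear in loading: ~0.8% per 1,000
#' recovered cells (the widely quoted figure for 10x-style chips), capped
#' at 50%.
#'
#' @param lib_cost_per_library Library preparation cost per library.
#' @param seq_cost_per_400M_reads Sequencing cost per 4e8 reads.
#' @param overhead_fraction Extra sequencing fraction lost to unaligned
#'   reads and adapters, in [0, 1).
#' @param reads_per_cell Reads needed per cell.
#' @param cells_per_sample_retained Desired cells per sample after
#'   discarding identifiable doublets.
#' @param doublet_rate_slope Doublet fraction per 1,000 recovered cells.
#' @return Object of class `cost_assumptions`.
#' @export
cost_assumptions <- function(lib_cost_per_library = 2000,
                             seq_cost_per_400M_reads = 1500,
                             overhead_fraction = 0.30,
                             reads_per_cell = 20000,
                             cells_per_sample_retained = 4000,
                             doublet_rate_slope = 0.008) {
  stopifnot(lib_cost_per_library > 0, seq_cost_per_400M_reads > 0,
            overhead_fraction >= 0, overhead_fraction < 1,
            reads_per_cell > 0, cells_per_sample_retained > 0,
            doublet_rate_slope >= 0)
  structure(list(lib_cost_per_library = lib_cost_per_library,
                 seq_cost_per_400M_reads = seq_cost_per_400M_reads,
                 overhead_fraction = overhead_fraction,
                 reads_per_cell = reads_per_cell,
                 cells_per_sample_retained = cells_per_sample_retained,
                 doublet_rate_slope = doublet_rate_slope),
            class = "cost_assumptions")
}

#' Sequencing cost for a number of reads
#'
#' Pro-rated continuously: n/4e8 x cost-per-400M x (1 + overhead).
#'
#' @param n_reads Number of reads (>= 0).
#' @param assumptions A [cost_assumptions()].
#' @return Cost in the assumption's currency units.
#' @export
sequencing_cost <- function(n_reads, assumptions = cost_assumptions()) {
  stopifnot(n_reads >= 0)
  n_reads / 4e8 * assumptions$seq_cost_per_400M_reads *
    (1 + assumptions$overhead_fraction)
}

#' Recovered cells needed in a super-loaded multiplexed run
#'
#' Solves for the smallest R with
#' R x (1 - D(R) x (n-1)/n) = n x cells_per_sample_retained,
#' where D(R) = doublet_rate_slope x R/1000 (capped at 0.5) is the droplet
#' doublet fraction at loading R and (n-1)/n is the identifiable fraction
#' of doublets under equal pool proportions (identifiable doublets are
#' discarded; same-donor doublets are kept). Solved by damped fixed-point
#' iteration to 1e-8 relative tolerance.
#'
#' @param n_samples Number of pooled samples (>= 1).
#' @param assumptions A [cost_assumptions()].
#' @return Recovered cell count R (real).
#' @export
recovered_cells_needed <- function(n_samples,
                                   assumptions = cost_assumptions()) {
  stopifnot(n_samples >= 1)
  target <- n_samples * assumptions$cells_per_sample_retained
  slope <- assumptions$doublet_rate_slope
  ident <- (n_samples - 1) / n_samples
  if (slope == 0 || ident == 0) return(target)
  fD <- function(R) min(slope * R / 1000, 0.5)
  R <- target
  for (it in seq_len(10000L)) {
    keep <- 1 - fD(R) * ident
    if (keep <= 0)
      stop("no solution: doublet losses exceed recovery at R = ",
           format(R, digits = 6))
    R_new <- 0.5 * R + 0.5 * target / keep
    if (abs(R_new - R) <= 1e-8 * R) {
      R <- R_new
      if (fD(R) >= 0.5 && abs(R * (1 - fD(R) * ident) - target) > 1e-6 * target)
        stop("no solution below the 50% doublet-rate cap")
      return(R)
    }
    R <- R_new
  }
  stop("fixed-point iteration did not converge")
}

#' Cost of one experimental design
#'
#' Unmultiplexed: n separate libraries, each sequenced for exactly
#' cells_per_sample_retained cells (without pooling, doublets cannot be
#' identified, so no discard overhead is budgeted). Multiplexed: one
#' library, super-loaded to recover [recovered_cells_needed()] cells so
#' that the retained cells after discarding identifiable doublets meet the
#' per-sample target.
#'
#' @param n_samples Number of samples.
#' @param multiplexed Logical: full multiplexing or no multiplexing.
#' @param assumptions A [cost_assumptions()].
#' @return List: design, n_samples, cells_sequenced, library_cost,
#'   sequencing_cost, total.
#' @export
experiment_cost <- function(n_samples, multiplexed,
                            assumptions = cost_assumptions()) {
  stopifnot(n_samples >= 1)
  if (multiplexed) {
    cells <- recovered_cells_needed(n_samples, assumptions)
    lib <- assumptions$lib_cost_per_library
    seq <- sequencing_cost(cells * assumptions$reads_per_cell, assumptions)
  } else {
    cells <- n_samples * assumptions$cells_per_sample_retained
    lib <- n_samples * assumptions$lib_cost_per_library
    seq <- n_samples * sequencing_cost(
      assumptions$cells_per_sample_retained * assumptions$reads_per_cell,
      assumptions)
  }
  list(design = if (multiplexed) "multiplexed" else "unmultiplexed",
       n_samples = n_samples, cells_sequenced = cells,
       library_cost = lib, sequencing_cost = seq, total = lib + seq)
}

#' Cost savings of full multiplexing versus no multiplexing
#'
#' @param n_samples Number of samples.
#' @param assumptions A [cost_assumptions()].
#' @return List of class `cost_report`: both design costs and
#'   `savings_percent` = 100 x (1 - multiplexed/unmultiplexed).
#' @export
cost_savings <- function(n_samples, assumptions = cost_assumptions()) {
  un <- experiment_cost(n_samples, FALSE, assumptions)
  mu <- experiment_cost(n_samples, TRUE, assumptions)
  structure(list(unmultiplexed = un, multiplexed = mu,
                 savings_percent = 100 * (1 - mu$total / un$total)),
            class = "cost_report")
}

#' Cost table over a range of pool sizes
#'
#' @param n_samples Integer vector of pool sizes (default 4:8).
#' @param assumptions A [cost_assumptions()].
#' @return Long-format data frame: n_samples, design, cells_sequenced,
#'   library_cost, sequencing_cost, total, savings_percent.
#' @export
cost_table <- function(n_samples = 4:8, assumptions = cost_assumptions()) {
  rows <- lapply(n_samples, function(n) {
    cs <- cost_savings(n, assumptions)
    do.call(rbind, lapply(list(cs$unmultiplexed, cs$multiplexed),
      function(x) data.frame(
        n_samples = n, design = x$design,
        cells_sequenced = x$cells_sequenced,
        library_cost = x$library_cost,
        sequencing_cost = x$sequencing_cost, total = x$total,
        savings_percent = cs$savings_percent)))
  })
  do.call(rbind, rows)
}
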