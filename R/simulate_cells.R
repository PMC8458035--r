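#' Cell-level simulation configuration
#'
#' @param cells_per_donor Integer vector, cells per donor (all >= 1).
#' @param mean_site_depth Mean reads covering a SNP site per cell. Real
#'   droplet data give sparse, shallow per-site coverage; the default of
#'   1 read/site/cell yields clean-pool demultiplexing that is essentially
#'   perfect, the intended best-case baseline.
#' @param depth_dispersion Lognormal sigma of the per-cell library size
#'   factor (0 = all cells equal).
#' @param error_rate Per-base sequencing error rate epsilon in [0, 0.5):
#'   the probability that a read reports the wrong allele.
#' @param seed Integer seed.
#' @return An object of class `cell_sim_config`.
#' @export
cell_sim_config <- function(cells_per_donor, mean_site_depth = 1.0,
                            depth_dispersion = 0.3, error_rate = 0.001,
                            seed = 1L) {
  stopifnot(length(cells_per_donor) >= 1, all(cells_per_donor >= 1),
            mean_site_depth > 0, depth_dispersion >= 0,
            error_rate >= 0, error_rate < 0.5)
  structure(list(cells_per_donor = as.integer(cells_per_donor),
                 mean_site_depth = mean_site_depth,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "cell_sim_config")
}

#' Allele count matrix (cellSNP-style AD/DP)
#'
#' Sparse barcodes x sites matrices of ALT-allele read counts (`AD`) and
#' total read depths (`DP`), with `0 <= AD <= DP` everywhere.
#'
#' @param barcodes Character vector of unique cell barcodes.
#' @param AD,DP Sparse (or coercible) matrices, barcodes in rows.
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(barcodes, AD, DP) {
  AD <- methods::as(methods::as(AD, "CsparseMatrix"), "dMatrix")
  DP <- methods::as(methods::as(DP, "CsparseMatrix"), "dMatrix")
  obj <- structure(list(barcodes = barcodes, AD = AD, DP = DP),
                   class = "allele_counts")
  validate_allele_counts(obj)
  obj
}

validate_allele_counts <- function(x) {
  stopifnot(inherits(x, "allele_counts"))
  if (anyDuplicated(x$barcodes)) stop("barcodes must be unique")
  if (length(x$barcodes) != nrow(x$AD) ||
      !all(dim(x$AD) == dim(x$DP)))
    stop("AD/DP dimensions must match the barcode list")
  if (any(x$AD@x < 0) || any(x$DP@x < 0))
    stop("counts must be nonnegative")
  if (any((x$AD - x$DP)@x > 0))
    stop("AD must not exceed DP")
  invisible(x)
}

#' @export
#' @method print allele_counts
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d barcodes x %d sites, %d nonzero depths\n",
              nrow(x$DP), ncol(x$DP), length(x$DP@x)))
  invisible(x)
}

#' Per-barcode ground-truth labels
#'
#' @param barcode Character barcodes.
#' @param label_type `"singlet"`, `"doublet"` or `"debris"` (reads
#'   redistributed, barcode removed from the count matrix).
#' @param donor_a,donor_b Integer donor indices; for doublets the pair is
#'   unordered and stored with `donor_a <= donor_b`; `donor_b` is `NA` for
#'   singlets and debris.
#' @param somatic_sites Per-barcode semicolon-joined site indices of
#'   somatic variants the cell carries (empty string when none).
#' @return Data frame of class `cell_truth`.
#' @export
cell_truth <- function(barcode, label_type, donor_a, donor_b = NA_integer_,
                       somatic_sites = "") {
  df <- data.frame(barcode = barcode, label_type = label_type,
                   donor_a = as.integer(donor_a),
                   donor_b = as.integer(donor_b),
                   somatic_sites = somatic_sites,
                   stringsAsFactors = FALSE)
  swap <- !is.na(df$donor_b) & df$donor_b < df$donor_a
  tmp <- df$donor_a[swap]
  df$donor_a[swap] <- df$donor_b[swap]
  df$donor_b[swap] <- tmp
  class(df) <- c("cell_truth", "data.frame")
  df
}

#' Simulate per-cell SNP allele counts for a pool of singlet cells
#'
#' For cell c of donor k at site v, depth d ~ Poisson(s_c * mean_site_depth)
#' with a lognormal per-cell size factor s_c, and the ALT count is
#' Binomial(d, pi) with pi = phi + eps(1 - 2 phi). The ALT fraction phi is
#' the CNV-aware override where present, g/2 otherwise; at a somatic site
#' the donor's cells carry the variant (phi = 1/2) with probability equal
#' to the event's clone fraction, recorded per cell in the truth table.
#'
#' @param genotypes A [donor_genotypes()].
#' @param panel The matching [snp_panel()].
#' @param config A [cell_sim_config()].
#' @return List with `counts` ([allele_counts()]) and `truth`
#'   ([cell_truth()]); all barcodes are singlets.
#' @export
simulate_cell_counts <- function(genotypes, panel, config) {
  validate_donor_genotypes(genotypes); validate_snp_panel(panel)
  stopifnot(inherits(config, "cell_sim_config"))
  K <- nrow(genotypes$G); V <- ncol(genotypes$G)
  if (V != nrow(panel)) stop("genotype/panel dimension mismatch")
  if (length(config$cells_per_donor) != K)
    stop("cells_per_donor length must equal the number of donors")
  C <- sum(config$cells_per_donor)
  donor_of_cell <- rep(seq_len(K), config$cells_per_donor)
  barcodes <- make_barcodes(C, derive_seed(config$seed, "barcodes"))
  eps <- config$error_rate

  with_rng(derive_seed(config$seed, "cell_counts"), {
    sf <- if (config$depth_dispersion > 0)
      stats::rlnorm(C, meanlog = -config$depth_dispersion^2 / 2,
                    sdlog = config$depth_dispersion)
    else rep(1, C)
    D <- matrix(stats::rpois(C * V, rep(sf * config$mean_site_depth, V)),
                nrow = C)
    phi_base <- effective_phi(genotypes, mode = "base")
    Phi <- phi_base[donor_of_cell, , drop = FALSE]
    somatic_sites <- rep("", C)
    se <- genotypes$somatic_events
    if (nrow(se)) {
      carrier_lists <- vector("list", C)
      for (i in seq_len(nrow(se))) {
        cells <- which(donor_of_cell == se$donor[i])
        Phi[cells, se$site[i]] <- 0  # non-carriers lack the variant
        carriers <- cells[stats::runif(length(cells)) < se$clone_fraction[i]]
        Phi[carriers, se$site[i]] <- 0.5
        for (cc in carriers)
          carrier_lists[[cc]] <- c(carrier_lists[[cc]], se$site[i])
      }
      somatic_sites <- vapply(carrier_lists, function(s)
        paste(sort(s), collapse = ";"), "")
    }
    Pi <- alt_prob(Phi, eps)
    A <- matrix(0L, C, V)
    nz <- D > 0
    A[nz] <- stats::rbinom(sum(nz), D[nz], Pi[nz])
    counts <- allele_counts(barcodes,
                            Matrix::drop0(Matrix::Matrix(A, sparse = TRUE)),
                            Matrix::drop0(Matrix::Matrix(D, sparse = TRUE)))
    truth <- cell_truth(barcodes, "singlet", donor_of_cell,
                        NA_integer_, somatic_sites)
    list(counts = counts, truth = truth)
  })
}
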