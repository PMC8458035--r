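#' Simulate matched bulk RNA-seq allele counts per donor
#'
#' Pooled read counts over each donor's cells: depth ~ Poisson(mean_depth)
#' per (donor, site) and ALT ~ Binomial(depth, pi) with
#' pi = phi + eps(1 - 2 phi). The donor's effective ALT fraction phi
#' includes CNV overrides; somatic sites enter at phi = c/2, the clonal
#' mixture of het carrier and non-carrier cells, so downstream genotype
#' calling can miscall them — mirroring real contamination of bulk-derived
#' references by somatic variation.
#'
#' @param genotypes A [donor_genotypes()].
#' @param panel The matching [snp_panel()].
#' @param mean_depth Mean bulk read depth per site.
#' @param error_rate Sequencing error rate.
#' @param seed Integer seed.
#' @return Object of class `bulk_counts`: `alt` and `depth` K x V matrices.
#' @export
simulate_bulk_counts <- function(genotypes, panel, mean_depth = 100,
                                 error_rate = 0.001, seed = 1L) {
  validate_donor_genotypes(genotypes); validate_snp_panel(panel)
  stopifnot(ncol(genotypes$G) == nrow(panel), mean_depth > 0,
            error_rate >= 0, error_rate < 0.5)
  K <- nrow(genotypes$G); V <- ncol(genotypes$G)
  with_rng(seed, {
    depth <- matrix(stats::rpois(K * V, mean_depth), K, V)
    phi <- effective_phi(genotypes, mode = "bulk")
    pi <- alt_prob(phi, error_rate)
    alt <- matrix(0L, K, V)
    nz <- depth > 0
    alt[nz] <- stats::rbinom(sum(nz), depth[nz], pi[nz])
    structure(list(alt = alt, depth = depth, donor_ids = genotypes$donor_ids),
              class = "bulk_counts")
  })
}

#' Call donor genotypes from bulk allele counts
#'
#' Depth-gated allele-fraction thresholding, a deliberately simple variant
#' caller standing in for a full pileup-based one: sites with depth below
#' `min_depth` are missing; otherwise AF = alt/depth is called 0 when
#' AF <= t, 2 when AF >= 1 - t, and het (1) in between.
#'
#' @param bulk A `bulk_counts` object.
#' @param min_depth Minimum depth for a call (default 10).
#' @param hom_threshold Homozygote AF threshold t in (0, 0.5), default 0.1.
#' @return A [donor_genotypes()] with possible missing entries.
#' @export
call_genotypes_from_bulk <- function(bulk, min_depth = 10L,
                                     hom_threshold = 0.1) {
  stopifnot(inherits(bulk, "bulk_counts"), min_depth >= 1,
            hom_threshold > 0, hom_threshold < 0.5)
  af <- bulk$alt / pmax(bulk$depth, 1L)
  G <- matrix(1L, nrow(af), ncol(af))
  G[af <= hom_threshold] <- 0L
  G[af >= 1 - hom_threshold] <- 2L
  G[bulk$depth < min_depth] <- NA_integer_
  donor_genotypes(G, donor_ids = bulk$donor_ids)
}

#' Restrict a panel to sites covered by the single-cell pool
#'
#' Emulates discovering usable SNP sites from the scRNA-seq data itself:
#' only sites with at least `min_total` pooled reads are retained.
#'
#' @param counts An [allele_counts()].
#' @param panel The matching [snp_panel()].
#' @param min_total Minimum pooled depth across all barcodes.
#' @return A [snp_panel()] subset with a `site_index` attribute.
#' @export
sites_with_coverage <- function(counts, panel, min_total = 1L) {
  validate_allele_counts(counts); validate_snp_panel(panel)
  stopifnot(ncol(counts$DP) == nrow(panel))
  keep <- which(Matrix::colSums(counts$DP) >= min_total)
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_panel", "data.frame")
  attr(out, "site_index") <- keep
  out
}
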