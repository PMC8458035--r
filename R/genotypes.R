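#' Donor genotype objects
#'
#' Holds a K donors x V sites genotype matrix with entries 0/1/2 (ALT allele
#' dosage) or `NA` (missing), plus two sparse annotations used to model
#' cancer genomes: `phi_override`, per-(donor, site) ALT-allele fractions
#' displaced from g/2 by copy-number imbalance, and `somatic_events`,
#' donor-private somatic SNVs with a subclone fraction.
#'
#' @param G Integer matrix, donors in rows, sites in columns.
#' @param phi_override Data frame (donor, site, phi) or NULL.
#' @param somatic_events Data frame (donor, site, clone_fraction) or NULL.
#' @param donor_ids Character donor labels (default `donor1..K`).
#' @return An object of class `donor_genotypes`.
#' @export
donor_genotypes <- function(G, phi_override = NULL, somatic_events = NULL,
                            donor_ids = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  if (is.null(donor_ids)) donor_ids <- paste0("donor", seq_len(nrow(G)))
  if (is.null(phi_override))
    phi_override <- data.frame(donor = integer(0), site = integer(0),
                               phi = numeric(0))
  if (is.null(somatic_events))
    somatic_events <- data.frame(donor = integer(0), site = integer(0),
                                 clone_fraction = numeric(0))
  obj <- structure(list(G = G, phi_override = phi_override,
                        somatic_events = somatic_events,
                        donor_ids = donor_ids),
                   class = "donor_genotypes")
  validate_donor_genotypes(obj)
  obj
}

validate_donor_genotypes <- function(geno) {
  stopifnot(inherits(geno, "donor_genotypes"))
  G <- geno$G
  vals <- G[!is.na(G)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotypes must be 0, 1, 2 or NA")
  ov <- geno$phi_override
  if (nrow(ov)) {
    stopifnot(all(ov$donor >= 1), all(ov$donor <= nrow(G)),
              all(ov$site >= 1), all(ov$site <= ncol(G)),
              all(ov$phi >= 0), all(ov$phi <= 1))
    if (any(is.na(G[cbind(ov$donor, ov$site)])))
      stop("phi overrides are only allowed at non-missing genotypes")
  }
  se <- geno$somatic_events
  if (nrow(se)) {
    stopifnot(all(se$donor >= 1), all(se$donor <= nrow(G)),
              all(se$site >= 1), all(se$site <= ncol(G)),
              all(se$clone_fraction > 0), all(se$clone_fraction <= 1))
    # donor-private: at a somatic site, only the event's donor carries ALT
    for (i in seq_len(nrow(se))) {
      g <- G[, se$site[i]]
      if (any(g[-se$donor[i]] != 0, na.rm = TRUE) || g[se$donor[i]] == 0)
        stop("somatic sites must be private to their donor")
    }
  }
  stopifnot(length(geno$donor_ids) == nrow(G))
  invisible(geno)
}

#' Sample donor genotypes under Hardy-Weinberg equilibrium
#'
#' Unrelated donors: at a site with population MAF q, genotypes are drawn
#' with probabilities ((1-q)^2, 2q(1-q), q^2) independently per donor.
#'
#' @param panel A [snp_panel()]; only germline sites are expected.
#' @param K Number of donors (>= 1).
#' @param seed Integer seed.
#' @return A [donor_genotypes()] with no missing entries.
#' @export
generate_donor_genotypes <- function(panel, K, seed = 1L) {
  validate_snp_panel(panel)
  stopifnot(K >= 1)
  V <- nrow(panel)
  q <- panel$maf
  with_rng(seed, {
    u <- matrix(stats::runif(K * V), nrow = K)
    p0 <- matrix((1 - q)^2, nrow = K, ncol = V, byrow = TRUE)
    p01 <- matrix((1 - q)^2 + 2 * q * (1 - q), nrow = K, ncol = V,
                  byrow = TRUE)
    G <- matrix(0L, K, V)
    G[u >= p0] <- 1L
    G[u >= p01] <- 2L
    donor_genotypes(G)
  })
}

#' Append donor-private somatic SNVs at a given tumor mutational burden
#'
#' For each donor, Poisson(tmb_per_mb x covered_mb) new sites are appended
#' to the panel with genotype 1 for that donor only, each with a subclone
#' fraction drawn from `clone_fraction_law` (the fraction of that donor's
#' cells carrying the variant). Original sites are untouched; the extended
#' panel is re-sorted by (chrom, pos) and all site indices remapped.
#'
#' @param genotypes A [donor_genotypes()].
#' @param panel The matching [snp_panel()].
#' @param tmb_per_mb Somatic mutations per megabase (>= 0).
#' @param covered_mb Megabases of transcribed sequence covered by the assay.
#' @param clone_fraction_law A [dist_uniform()] spec over (0, 1].
#' @param seed Integer seed.
#' @return List with elements `genotypes` and `panel`, both extended.
#' @export
apply_somatic_snvs <- function(genotypes, panel, tmb_per_mb, covered_mb,
                               clone_fraction_law = dist_uniform(0.2, 1.0),
                               seed = 1L) {
  validate_donor_genotypes(genotypes); validate_snp_panel(panel)
  stopifnot(tmb_per_mb >= 0, covered_mb > 0, ncol(genotypes$G) == nrow(panel))
  K <- nrow(genotypes$G)
  with_rng(seed, {
    n_new <- stats::rpois(K, tmb_per_mb * covered_mb)
    total <- sum(n_new)
    if (total == 0) return(list(genotypes = genotypes, panel = panel))
    bases <- c("A", "C", "G", "T")
    chrom <- as.character(sample.int(22L, total, replace = TRUE))
    pos <- sample.int(1e8L, total, replace = TRUE)
    repeat {
      dup <- duplicated(c(paste(panel$chrom, panel$pos),
                          paste(chrom, pos)))[nrow(panel) + seq_len(total)]
      if (!any(dup)) break
      pos[dup] <- sample.int(1e8L, sum(dup), replace = TRUE)
    }
    ref <- sample(bases, total, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    new_panel <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      maf = NA_real_, region_tag = "other", origin = "somatic",
      stringsAsFactors = FALSE)
    ext <- rbind(as.data.frame(panel), new_panel)
    donor_of_new <- rep(seq_len(K), n_new)
    G_new <- matrix(0L, K, total)
    G_new[cbind(donor_of_new, seq_len(total))] <- 1L
    G_ext <- cbind(genotypes$G, G_new)
    events <- data.frame(
      donor = donor_of_new,
      site = nrow(panel) + seq_len(total),
      clone_fraction = draw_dist(clone_fraction_law, total))
    events <- rbind(genotypes$somatic_events, events)
    # re-sort to keep the (chrom, pos) panel invariant; remap site indices
    ord <- panel_order(ext$chrom, ext$pos)
    rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
    ext <- ext[ord, , drop = FALSE]
    G_ext <- G_ext[, ord, drop = FALSE]
    ov <- genotypes$phi_override
    if (nrow(ov)) ov$site <- rank[ov$site]
    if (nrow(events)) events$site <- rank[events$site]
    list(genotypes = donor_genotypes(G_ext, ov, events,
                                     genotypes$donor_ids),
         panel = snp_panel(ext))
  })
}

#' Skew heterozygous allele fractions to emulate CNV burden
#'
#' Copy-number imbalance at a heterozygous site moves the ALT-allele
#' fraction from 1/2 to major/(major+minor) or minor/(major+minor),
#' depending on which haplotype carries the ALT allele (fair coin).
#' Homozygous sites are untouched: ALT fraction 0 or 1 is invariant to
#' copy number.
#'
#' @param genotypes A [donor_genotypes()].
#' @param fraction_of_sites Fraction of each donor's het sites affected.
#' @param copy_states List of integer pairs (major, minor) copy numbers,
#'   sampled uniformly per affected site; `major + minor >= 1`.
#' @param seed Integer seed.
#' @return A [donor_genotypes()] with `phi_override` populated.
#' @export
apply_cnv_allele_skew <- function(genotypes, fraction_of_sites,
                                  copy_states = list(c(2L, 1L), c(3L, 1L)),
                                  seed = 1L) {
  validate_donor_genotypes(genotypes)
  stopifnot(fraction_of_sites >= 0, fraction_of_sites <= 1)
  for (cs in copy_states)
    stopifnot(length(cs) == 2, all(cs >= 0), sum(cs) >= 1)
  if (fraction_of_sites == 0) return(genotypes)
  K <- nrow(genotypes$G)
  with_rng(seed, {
    ov <- genotypes$phi_override
    for (k in seq_len(K)) {
      het <- which(!is.na(genotypes$G[k, ]) & genotypes$G[k, ] == 1L)
      n_aff <- round_half_away(fraction_of_sites * length(het))
      if (n_aff == 0) next
      sites <- sample(het, n_aff)
      cs_idx <- sample.int(length(copy_states), n_aff, replace = TRUE)
      major_on_alt <- stats::runif(n_aff) < 0.5
      phi <- vapply(seq_len(n_aff), function(i) {
        cs <- copy_states[[cs_idx[i]]]
        if (major_on_alt[i]) cs[1] / sum(cs) else cs[2] / sum(cs)
      }, numeric(1))
      ov <- rbind(ov, data.frame(donor = k, site = sites, phi = phi))
    }
    donor_genotypes(genotypes$G, ov, genotypes$somatic_events,
                    genotypes$donor_ids)
  })
}

#' Subset a genotype object to a site mask
#'
#' Companion to [filter_panel_by_region()], [intersect_panels()] and
#' [sample_array_panel()]: applies the same column mask to the genotype
#' matrix, remapping override and somatic-event site indices (events whose
#' site is dropped are removed).
#'
#' @param genotypes A [donor_genotypes()].
#' @param site_index Integer indices of sites to keep (e.g. the
#'   `site_index` attribute of a filtered panel).
#' @return A [donor_genotypes()] over the retained sites.
#' @export
subset_genotypes <- function(genotypes, site_index) {
  validate_donor_genotypes(genotypes)
  stopifnot(all(site_index >= 1), all(site_index <= ncol(genotypes$G)))
  rank <- rep(NA_integer_, ncol(genotypes$G))
  rank[site_index] <- seq_along(site_index)
  remap <- function(df) {
    df$site <- rank[df$site]
    df[!is.na(df$site), , drop = FALSE]
  }
  donor_genotypes(genotypes$G[, site_index, drop = FALSE],
                  remap(genotypes$phi_override),
                  remap(genotypes$somatic_events),
                  genotypes$donor_ids)
}

#' Drop genotype information, keeping only the site list
#'
#' Produces the sites-only reference consumed by genotype-free
#' demultiplexing, which infers donor allele fractions directly from the
#' single-cell counts.
#'
#' @param genotypes A [donor_genotypes()] (discarded).
#' @param panel The matching [snp_panel()].
#' @return The panel, with no genotype information attached.
#' @export
strip_genotypes <- function(genotypes, panel) {
  validate_snp_panel(panel)
  if (!is.null(genotypes)) {
    validate_donor_genotypes(genotypes)
    stopifnot(ncol(genotypes$G) == nrow(panel))
  }
  out <- as.data.frame(panel)
  snp_panel(out)
}

# Effective per-(donor, site) ALT fraction.
# mode "bulk": somatic sites enter at phi = c/2 (clonal mixture of het
# carriers and non-carriers across the donor's cells).
# mode "base": overrides applied, somatic handled per cell by the caller.
effective_phi <- function(genotypes, mode = c("base", "bulk")) {
  mode <- match.arg(mode)
  phi <- genotypes$G / 2
  ov <- genotypes$phi_override
  if (nrow(ov)) phi[cbind(ov$donor, ov$site)] <- ov$phi
  if (mode == "bulk") {
    se <- genotypes$somatic_events
    if (nrow(se))
      phi[cbind(se$donor, se$site)] <- se$clone_fraction / 2
  }
  phi
}
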