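# Independent oracles and fixture builders. These deliberately use naive,
# loop-based code paths distinct from the package implementation.

# Brute-force class-enumeration posterior for genotype-aware
# demultiplexing: per barcode, loop over sites with dbinom per site.
oracle_posterior <- function(AD, DP, G, eps, delta) {
  AD <- as.matrix(AD); DP <- as.matrix(DP)
  K <- nrow(G)
  classes <- list()
  for (k in seq_len(K))
    classes[[length(classes) + 1L]] <- list(type = "singlet", i = k)
  if (K >= 2)
    for (i in seq_len(K - 1)) for (j in (i + 1):K)
      classes[[length(classes) + 1L]] <- list(type = "doublet", i = i, j = j)
  n_pairs <- K * (K - 1) / 2
  priors <- c(rep((1 - delta) / K, K),
              if (n_pairs > 0) rep(delta / n_pairs, n_pairs))
  post <- matrix(NA_real_, nrow(AD), length(classes))
  for (c in seq_len(nrow(AD))) {
    ll <- vapply(classes, function(cl) {
      tot <- 0
      for (v in seq_len(ncol(AD))) {
        if (DP[c, v] == 0) next
        if (cl$type == "singlet") {
          g <- G[cl$i, v]
          if (is.na(g)) next
          p <- g / 2 + eps * (1 - g)
        } else {
          gi <- G[cl$i, v]; gj <- G[cl$j, v]
          if (is.na(gi) || is.na(gj)) next
          pi_i <- gi / 2 + eps * (1 - gi)
          pi_j <- gj / 2 + eps * (1 - gj)
          p <- (pi_i + pi_j) / 2
        }
        p <- min(max(p, 1e-12), 1 - 1e-12)
        tot <- tot + dbinom(AD[c, v], DP[c, v], p, log = TRUE)
      }
      tot
    }, numeric(1))
    w <- exp(ll + log(priors) - max(ll + log(priors)))
    post[c, ] <- w / sum(w)
  }
  post
}

# Independent donor-matching scorer: counts correct singlets barcode by
# barcode for an explicit permutation.
oracle_matching_score <- function(result, truth, perm) {
  score <- 0L
  for (i in seq_len(nrow(truth))) {
    if (truth$label_type[i] != "singlet") next
    r <- result[result$barcode == truth$barcode[i], ]
    if (nrow(r) == 1 && r$call == "singlet" && !is.na(r$donor_a) &&
        perm[r$donor_a] == truth$donor_a[i])
      score <- score + 1L
  }
  score
}

# Minimal demux_result for hand-built evaluation fixtures.
make_result <- function(barcode, call, donor_a = NA_integer_,
                        donor_b = NA_integer_, K = 2L) {
  res <- data.frame(barcode = barcode, call = call,
                    donor = ifelse(call == "singlet",
                                   paste0("donor", donor_a), NA_character_),
                    donor_a = as.integer(donor_a),
                    donor_b = as.integer(donor_b),
                    max_posterior = 1, stringsAsFactors = FALSE)
  class(res) <- c("demux_result", "data.frame")
  attr(res, "posterior") <- matrix(1, nrow(res), 1)
  attr(res, "donor_ids") <- paste0("donor", seq_len(K))
  res
}

# A panel with constant MAF at hand-picked sites (chrom "1", pos 1..n).
flat_panel <- function(n, maf = 0.3, region = "other") {
  snp_panel(data.frame(
    chrom = "1", pos = seq_len(n), ref = "A", alt = "G", maf = maf,
    region_tag = rep_len(region, n), origin = "germline",
    stringsAsFactors = FALSE))
}

# Small pooled dataset: K donors, distinct genotypes from HWE, singlet
# counts at a depth that separates donors well.
toy_pool <- function(K = 3, cells = 30, V = 200, depth = 1, seed = 1,
                     eps = 0.001) {
  panel <- generate_snp_panel(V, seed = seed)
  geno <- generate_donor_genotypes(panel, K, seed = seed + 1)
  sim <- simulate_cell_counts(geno, panel, cell_sim_config(
    rep(cells, K), mean_site_depth = depth, error_rate = eps,
    seed = seed + 2))
  list(panel = panel, geno = geno, counts = sim$counts, truth = sim$truth)
}
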