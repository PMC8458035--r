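test_that("SNP panel generation respects size, bounds, ordering and seed", {
  expect_equal(nrow(generate_snp_panel(0)), 0L)

  panel <- generate_snp_panel(2000, utr_fraction = 0.1, seed = 42)
  expect_equal(nrow(panel), 2000L)
  expect_true(all(panel$maf > 0 & panel$maf <= 0.5))
  # strictly increasing positions within each chromosome
  for (ch in unique(panel$chrom))
    expect_true(all(diff(panel$pos[panel$chrom == ch]) > 0))
  # tagged count within the central 99% binomial interval around 200
  n_utr <- sum(panel$region_tag == "three_prime_utr")
  expect_gte(n_utr, qbinom(0.005, 2000, 0.1))
  expect_lte(n_utr, qbinom(0.995, 2000, 0.1))
  # deterministic per seed
  expect_identical(panel, generate_snp_panel(2000, utr_fraction = 0.1,
                                             seed = 42))
  expect_error(generate_snp_panel(10, maf_law = dist_uniform(0.1, 0.7)),
               "maf_law")
})

test_that("donor genotypes follow Hardy-Weinberg proportions", {
  # limiting cases
  tiny <- flat_panel(500, maf = 1e-6)
  g0 <- generate_donor_genotypes(tiny, 2, seed = 1)
  expect_true(mean(g0$G == 0) > 0.999)
  half <- flat_panel(2000, maf = 0.5)
  g5 <- generate_donor_genotypes(half, 1, seed = 2)
  expect_equal(mean(g5$G), 1, tolerance = 0.05)
  # closed-form HWE oracle at q = 0.2 via chi-square goodness of fit
  p02 <- flat_panel(10000, maf = 0.2)
  g <- generate_donor_genotypes(p02, 1, seed = 3)
  counts <- table(factor(g$G, levels = 0:2))
  fit <- chisq.test(counts, p = c(0.64, 0.32, 0.04))
  expect_gt(fit$p.value, 0.01)
  expect_false(anyNA(g$G))
})

test_that("somatic SNVs are donor-private Poisson appendages", {
  panel <- generate_snp_panel(200, seed = 5)
  geno <- generate_donor_genotypes(panel, 3, seed = 5)
  # null case
  ext0 <- apply_somatic_snvs(geno, panel, 0, 50, seed = 1)
  expect_identical(ext0$panel, panel)
  expect_identical(ext0$genotypes$G, geno$G)

  ext <- apply_somatic_snvs(geno, panel, 20, 50, seed = 9)
  n_new <- nrow(ext$panel) - nrow(panel)
  # total appended sites within the central 99% interval of Poisson(3000)
  expect_gte(n_new, qpois(0.005, 3000))
  expect_lte(n_new, qpois(0.995, 3000))
  # every appended site has exactly one donor with nonzero genotype
  som <- which(ext$panel$origin == "somatic")
  expect_equal(length(som), n_new)
  expect_true(all(colSums(ext$genotypes$G[, som, drop = FALSE] > 0) == 1))
  # original germline records survive unchanged (possibly reordered)
  germ <- ext$panel[ext$panel$origin == "germline", ]
  expect_setequal(paste(germ$chrom, germ$pos, germ$ref, germ$alt),
                  paste(panel$chrom, panel$pos, panel$ref, panel$alt))
  validate_snp_panel(ext$panel)
  expect_true(all(ext$genotypes$somatic_events$clone_fraction > 0.2 - 1e-9 &
                    ext$genotypes$somatic_events$clone_fraction <= 1))
})

test_that("CNV skew overrides only het sites with the copy-state fractions", {
  panel <- generate_snp_panel(400, seed = 6)
  geno <- generate_donor_genotypes(panel, 2, seed = 6)
  expect_identical(apply_cnv_allele_skew(geno, 0), geno)
  sk <- apply_cnv_allele_skew(geno, 0.5, copy_states = list(c(2L, 1L)),
                              seed = 3)
  ov <- sk$phi_override
  expect_gt(nrow(ov), 0)
  expect_true(all(abs(ov$phi - 2 / 3) < 1e-12 | abs(ov$phi - 1 / 3) < 1e-12))
  expect_true(all(geno$G[cbind(ov$donor, ov$site)] == 1L))
  # roughly half of each donor's het sites affected
  for (k in 1:2) {
    n_het <- sum(geno$G[k, ] == 1L)
    expect_lte(abs(sum(ov$donor == k) - 0.5 * n_het), 1)
  }
})

test_that("cell counts follow the binomial read model", {
  # degenerate genotypes with zero error
  panel <- flat_panel(50)
  K <- 2
  for (gval in c(0L, 2L)) {
    geno <- donor_genotypes(matrix(gval, K, 50))
    sim <- simulate_cell_counts(geno, panel, cell_sim_config(
      c(10, 10), mean_site_depth = 3, error_rate = 0, seed = 4))
    if (gval == 0L) expect_equal(sum(sim$counts$AD), 0)
    else expect_equal(as.matrix(sim$counts$AD), as.matrix(sim$counts$DP))
  }
  # het sites: pooled ALT fraction ~ 0.5 exactly for any error rate
  geno <- donor_genotypes(matrix(1L, 1, 50))
  sim <- simulate_cell_counts(geno, panel, cell_sim_config(
    2000, mean_site_depth = 2, error_rate = 0.01, seed = 11))
  tot_d <- sum(sim$counts$DP)
  expect_gt(tot_d, 1e5)
  frac <- sum(sim$counts$AD) / tot_d
  ci <- 2.576 * sqrt(0.25 / tot_d)
  expect_lt(abs(frac - 0.5), ci)
  # bit-reproducible under the seed
  sim2 <- simulate_cell_counts(geno, panel, cell_sim_config(
    2000, mean_site_depth = 2, error_rate = 0.01, seed = 11))
  expect_identical(as.matrix(sim$counts$AD), as.matrix(sim2$counts$AD))
  expect_identical(sim$counts$barcodes, sim2$counts$barcodes)
})

test_that("somatic carrier cells are recorded and converge to the clone fraction", {
  panel <- generate_snp_panel(50, seed = 2)
  geno <- generate_donor_genotypes(panel, 2, seed = 2)
  ext <- apply_somatic_snvs(geno, panel, 0.04, 50,
                            clone_fraction_law = dist_uniform(0.599, 0.601),
                            seed = 21)
  ev <- ext$genotypes$somatic_events
  expect_gt(nrow(ev), 0)
  sim <- simulate_cell_counts(ext$genotypes, ext$panel, cell_sim_config(
    c(1500, 1500), mean_site_depth = 0.2, seed = 8))
  ev1 <- ev[1, ]
  carriers <- vapply(strsplit(sim$truth$somatic_sites, ";"), function(s)
    as.character(ev1$site) %in% s, logical(1))
  in_donor <- sim$truth$donor_a == ev1$donor
  expect_true(all(!carriers[!in_donor]))
  frac <- mean(carriers[in_donor])
  ci <- 2.576 * sqrt(0.6 * 0.4 / sum(in_donor))
  expect_lt(abs(frac - 0.6), ci + 0.002)
})

test_that("allele count matrices always satisfy 0 <= AD <= DP", {
  pool <- toy_pool(K = 3, cells = 20, V = 100, seed = 13)
  diffs <- (pool$counts$DP - pool$counts$AD)
  expect_true(all(diffs@x >= 0))
  expect_true(all(pool$counts$AD@x >= 0))
  expect_error(allele_counts("b1", matrix(2), matrix(1)), "exceed")
})
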