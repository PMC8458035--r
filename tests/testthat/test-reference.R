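test_that("bulk counts follow the donor allele fractions", {
  panel <- flat_panel(200)
  for (gval in c(0L, 2L)) {
    geno <- donor_genotypes(matrix(gval, 2, 200))
    bulk <- simulate_bulk_counts(geno, panel, mean_depth = 30,
                                 error_rate = 0, seed = 3)
    if (gval == 0L) expect_true(all(bulk$alt == 0))
    else expect_equal(bulk$alt, bulk$depth)
  }
  # het sites concentrate near AF 0.5 at high depth
  geno <- donor_genotypes(matrix(1L, 1, 200))
  bulk <- simulate_bulk_counts(geno, panel, mean_depth = 200,
                               error_rate = 0.001, seed = 4)
  tot <- sum(bulk$depth)
  expect_lt(abs(sum(bulk$alt) / tot - 0.5), 2.576 * sqrt(0.25 / tot))
})

test_that("bulk genotype calling applies the depth gate and AF thresholds", {
  bulk <- structure(list(alt = matrix(c(1L, 45L, 20L, 3L), 1),
                         depth = matrix(c(50L, 50L, 50L, 5L), 1),
                         donor_ids = "donor1"), class = "bulk_counts")
  g <- call_genotypes_from_bulk(bulk, min_depth = 10, hom_threshold = 0.1)
  expect_equal(as.integer(g$G), c(0L, 2L, 1L, NA))
  # monotone in depth: a confident call never becomes missing as depth
  # grows at the same allele fraction
  af <- 0.3
  for (d in c(10L, 50L, 500L)) {
    b <- structure(list(alt = matrix(as.integer(af * d), 1),
                        depth = matrix(d, 1), donor_ids = "d"),
                   class = "bulk_counts")
    expect_false(is.na(call_genotypes_from_bulk(b)$G[1, 1]))
  }
})

test_that("genotypes recovered from simulated bulk are highly concordant", {
  panel <- generate_snp_panel(5000, seed = 31)
  geno <- generate_donor_genotypes(panel, 3, seed = 31)
  bulk <- simulate_bulk_counts(geno, panel, mean_depth = 100,
                               error_rate = 0.01, seed = 32)
  called <- call_genotypes_from_bulk(bulk)
  conc <- mean(called$G == geno$G, na.rm = TRUE)
  expect_gte(conc, 0.99)
  # recovery accuracy is non-decreasing in bulk depth
  bulk20 <- simulate_bulk_counts(geno, panel, mean_depth = 20,
                                 error_rate = 0.01, seed = 33)
  conc20 <- mean(call_genotypes_from_bulk(bulk20)$G == geno$G, na.rm = TRUE)
  expect_gte(conc, conc20)
})

test_that("region filtering and panel intersection behave as set operations", {
  panel <- generate_snp_panel(100, utr_fraction = 0.4, seed = 41)
  expect_equal(
    as.data.frame(filter_panel_by_region(panel,
                                         c("three_prime_utr", "other"))),
    as.data.frame(panel), ignore_attr = TRUE)
  expect_equal(nrow(filter_panel_by_region(panel, character(0))), 0L)
  # hand fixture: 3 of 5 sites tagged, original order preserved
  p5 <- snp_panel(data.frame(
    chrom = "1", pos = 1:5, ref = "A", alt = "C", maf = 0.2,
    region_tag = c("three_prime_utr", "other", "three_prime_utr", "other",
                   "three_prime_utr"),
    origin = "germline", stringsAsFactors = FALSE))
  f <- filter_panel_by_region(p5, "three_prime_utr")
  expect_equal(f$pos, c(1L, 3L, 5L))
  expect_equal(attr(f, "site_index"), c(1L, 3L, 5L))

  # intersection: idempotence, disjointness, symmetry of membership
  expect_equal(as.data.frame(intersect_panels(panel, panel)),
               as.data.frame(panel), ignore_attr = TRUE)
  a <- panel[1:60, ]; b <- panel[41:100, ]
  class(a) <- class(b) <- c("snp_panel", "data.frame")
  ab <- intersect_panels(a, b)
  expect_equal(nrow(ab), 20L)
  expect_equal(nrow(ab), nrow(intersect_panels(b, a)))
  disj <- intersect_panels(panel[1:50, ], panel[51:100, ])
  expect_equal(nrow(disj), 0L)
  # conflicting alleles at a shared position are excluded with a message
  b2 <- as.data.frame(a)
  b2$alt[1] <- setdiff(c("A", "C", "G", "T"), c(b2$ref[1], b2$alt[1]))[1]
  b2 <- snp_panel(b2)
  expect_message(res <- intersect_panels(a, b2), "conflicting")
  expect_equal(nrow(res), nrow(a) - 1L)

  # filtering then intersecting equals intersecting then filtering
  fi <- intersect_panels(filter_panel_by_region(a, "three_prime_utr"),
                         filter_panel_by_region(b, "three_prime_utr"))
  if_ <- filter_panel_by_region(intersect_panels(a, b), "three_prime_utr")
  expect_identical(panel_key(fi), panel_key(if_))
  # intersection size bound
  expect_lte(nrow(ab), min(nrow(a), nrow(b)))
})

test_that("genotype subsetting follows the panel mask", {
  panel <- generate_snp_panel(50, seed = 51)
  geno <- generate_donor_genotypes(panel, 2, seed = 51)
  geno <- apply_cnv_allele_skew(geno, 0.5, seed = 52)
  f <- filter_panel_by_region(panel, "three_prime_utr")
  sub <- subset_genotypes(geno, attr(f, "site_index"))
  expect_equal(ncol(sub$G), nrow(f))
  expect_equal(unname(sub$G), unname(geno$G[, attr(f, "site_index")]))
  # overrides land on the same (donor, site) pairs after remapping
  ov <- sub$phi_override
  if (nrow(ov)) {
    orig <- geno$phi_override
    orig_kept <- orig[orig$site %in% attr(f, "site_index"), ]
    expect_equal(nrow(ov), nrow(orig_kept))
    expect_equal(sub$G[cbind(ov$donor, ov$site)],
                 geno$G[cbind(orig_kept$donor, orig_kept$site)])
  }
})

test_that("strip_genotypes returns a bare sites list", {
  panel <- generate_snp_panel(30, seed = 61)
  geno <- generate_donor_genotypes(panel, 2, seed = 61)
  sites <- strip_genotypes(geno, panel)
  expect_equal(nrow(sites), nrow(panel))
  expect_identical(panel_key(sites), panel_key(panel))
})
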