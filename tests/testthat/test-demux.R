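test_that("singlet log-likelihood matches per-site binomial arithmetic", {
  expect_equal(singlet_loglik(integer(0), integer(0), integer(0), 0.01), 0)
  expect_equal(singlet_loglik(c(0, 0), c(0, 0), c(1L, 2L), 0.01), 0)
  expect_equal(singlet_loglik(1, 1, 2L, 0.01), log(0.99))
  # 5-site case against a brute-force per-site pmf oracle
  a <- c(2L, 0L, 1L, 3L, 1L); d <- c(3L, 2L, 1L, 4L, 2L)
  g <- c(1L, 0L, 2L, 1L, NA)
  eps <- 0.02
  oracle <- 0
  for (v in 1:4) {  # site 5 has missing genotype and must be skipped
    p <- g[v] / 2 + eps * (1 - g[v])
    oracle <- oracle + log(choose(d[v], a[v]) * p^a[v] * (1 - p)^(d[v] - a[v]))
  }
  expect_equal(singlet_loglik(a, d, g, eps), oracle, tolerance = 1e-10)
  expect_error(singlet_loglik(2, 1, 1L, 0), "exceed")
})

test_that("doublet log-likelihood is the equal-mixture model", {
  a <- c(1L, 2L); d <- c(2L, 3L); g <- c(1L, 2L)
  expect_equal(doublet_loglik(a, d, g, g, 0.01),
               singlet_loglik(a, d, g, 0.01))
  expect_equal(doublet_loglik(a, d, c(0L, 1L), c(2L, 2L), 0.01),
               doublet_loglik(a, d, c(2L, 2L), c(0L, 1L), 0.01))
  # one site, d=2, a=1, genotypes 0 and 2, no error: pi = 0.5
  expect_equal(doublet_loglik(1, 2, 0L, 2L, 0), log(0.5))
})

test_that("posterior assignment agrees with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:3) {
    K <- sample(3:5, 1); V <- 10; C <- 20
    panel <- flat_panel(V)
    G <- matrix(sample(0:2, K * V, replace = TRUE), K, V)
    G[sample(length(G), 5)] <- NA  # missing reference entries
    D <- matrix(rpois(C * V, 1.5), C, V)
    D[1, ] <- 0L  # a zero-depth barcode
    A <- matrix(rbinom(C * V, D, 0.4), C, V)
    counts <- allele_counts(sprintf("b%02d", 1:C),
                            Matrix::Matrix(A, sparse = TRUE),
                            Matrix::Matrix(D, sparse = TRUE))
    ref <- donor_genotypes(G)
    eps <- 0.01; delta <- 0.1
    res <- demux_with_genotypes(counts, panel, ref, config = demux_config(
      error_rate = eps, doublet_prior = delta, K = K))
    post <- attr(res, "posterior")
    expect_equal(dim(post), c(C, K + K * (K - 1) / 2))
    # normalization
    expect_equal(rowSums(post), rep(1, C), tolerance = 1e-12)
    # oracle agreement to 1e-8
    expect_equal(post, oracle_posterior(A, D, G, eps, delta),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # zero-depth barcode: posterior equals the prior, hence unassigned
    expect_equal(res$call[1], "unassigned")
    expect_equal(max(post[1, ]), (1 - delta) / K, tolerance = 1e-12)
  }
})

test_that("calls are invariant to site permutation", {
  pool <- toy_pool(K = 3, cells = 10, V = 100, seed = 71)
  cfg <- demux_config(K = 3)
  res1 <- demux_with_genotypes(pool$counts, pool$panel, pool$geno,
                               config = cfg)
  set.seed(7)
  perm <- sample(100)
  counts_p <- allele_counts(pool$counts$barcodes,
                            pool$counts$AD[, perm], pool$counts$DP[, perm])
  geno_p <- donor_genotypes(pool$geno$G[, perm])
  res2 <- demux_with_genotypes(counts_p, pool$panel, geno_p,
                               ref_panel = NULL, config = cfg)
  expect_identical(res1$call, res2$call)
  expect_identical(res1$donor_a, res2$donor_a)
  expect_equal(res1$max_posterior, res2$max_posterior, tolerance = 1e-12)
})

test_that("genotype-aware demultiplexing recovers singlets and doublets", {
  pool <- toy_pool(K = 3, cells = 40, V = 300, seed = 81, depth = 1)
  cfg <- demux_config(error_rate = 0.001, doublet_prior = 0.05,
                      assign_threshold = 0.9, K = 3)
  res <- demux_with_genotypes(pool$counts, pool$panel, pool$geno,
                              config = cfg)
  tr <- pool$truth
  sing <- res$call == "singlet"
  expect_gt(mean(sing), 0.95)
  expect_true(all(res$donor_a[sing] == tr$donor_a[sing]))
  expect_gt(min(res$max_posterior[sing]), 0.99)
  # a barcode built as the sum of a donor-1 and donor-2 cell is called as
  # that doublet pair
  i <- which(tr$donor_a == 1)[1]; j <- which(tr$donor_a == 2)[1]
  AD2 <- rbind(pool$counts$AD[i, ] + pool$counts$AD[j, ])
  DP2 <- rbind(pool$counts$DP[i, ] + pool$counts$DP[j, ])
  res2 <- demux_with_genotypes(
    allele_counts("DBLT", Matrix::Matrix(AD2, sparse = TRUE),
                  Matrix::Matrix(DP2, sparse = TRUE)),
    pool$panel, pool$geno, config = cfg)
  expect_equal(res2$call, "doublet")
  expect_equal(c(res2$donor_a, res2$donor_b), c(1L, 2L))
  expect_error(demux_with_genotypes(
    pool$counts, pool$panel, donor_genotypes(pool$geno$G[1, , drop = FALSE]),
    config = cfg), "2 donors")
})

test_that("genotype-free EM has a monotone objective and recovers donors", {
  pool <- toy_pool(K = 2, cells = 40, V = 1000, seed = 91, depth = 1)
  cfg <- demux_config(K = 2, doublet_prior = 0.05, n_init = 3, seed = 5)
  fit <- demux_genotype_free(pool$counts, pool$panel, cfg)
  # objective trace is non-decreasing within every restart
  for (tr in fit$model$traces)
    expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  # 100% singlet accuracy after label matching
  mapping <- match_donor_labels(fit$result, pool$truth)
  res <- apply_donor_mapping(fit$result, mapping)
  sing_true <- pool$truth$label_type == "singlet"
  expect_equal(mean(res$call[sing_true] == "singlet" &
                      res$donor_a[sing_true] ==
                        pool$truth$donor_a[sing_true]), 1.0)
  # inferred allele fractions approach g/2 at well-covered sites
  # (order(mapping) inverts the inferred-to-true permutation)
  theta <- fit$model$theta[order(mapping), , drop = FALSE]
  covered <- Matrix::colSums(pool$counts$DP) >= 25
  err <- abs(theta[, covered, drop = FALSE] -
               pool$geno$G[, covered, drop = FALSE] / 2)
  expect_lt(mean(err), 0.05)
})

test_that("genotype-free edge cases: single class and posterior rules", {
  pool <- toy_pool(K = 2, cells = 10, V = 50, seed = 101)
  fit1 <- demux_genotype_free(pool$counts, pool$panel,
                              demux_config(K = 1, doublet_prior = 0))
  expect_true(all(fit1$result$donor_a == 1L))
  expect_true(all(fit1$result$call == "singlet"))
  post <- attr(fit1$result, "posterior")
  expect_equal(rowSums(post), rep(1, nrow(post)))
  expect_error(demux_genotype_free(pool$counts, pool$panel,
                                   demux_config(K = 50, doublet_prior = 0)),
               "more donors")
})
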