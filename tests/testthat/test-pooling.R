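test_that("doublet planner reproduces targets and matches exhaustive search", {
  # worked example: 15,202 cells at a 30% target
  expect_identical(n_doublets_for_target(15202, 0.30), 3508L)
  expect_identical(15202L - n_doublets_for_target(15202, 0.30), 11694L)
  expect_identical(n_doublets_for_target(500, 0), 0L)
  expect_identical(n_doublets_for_target(100, 0.25), 20L)
  expect_error(n_doublets_for_target(100, 1), "< 1")
  # exhaustive-search oracle over a grid of (N, p)
  for (N in c(7L, 50L, 313L)) for (p in c(0.05, 0.2, 0.3, 0.45)) {
    d_all <- 0:(N - 1L)
    obj <- abs(d_all / (N - d_all) - p)
    d_star <- d_all[which.min(obj)]  # first min = smallest d on ties
    d_pkg <- n_doublets_for_target(N, p)
    expect_identical(d_pkg, as.integer(d_star))
    # best-achievable rounding bound
    expect_lte(abs(d_pkg / (N - d_pkg) - p), 1 / (N - d_pkg))
  }
})

test_that("doublet merges are additive, conservative and correctly labelled", {
  pool <- toy_pool(K = 3, cells = 40, V = 80, seed = 17)
  db <- simulate_doublets(pool$counts, pool$truth, 0.25, seed = 5)
  d <- n_doublets_for_target(120, 0.25)
  expect_equal(nrow(db$plan), d)
  expect_equal(length(db$counts$barcodes), 120 - d)
  # truth doublet labels among final barcodes are exactly d
  expect_equal(sum(db$truth$label_type == "doublet"), d)
  # sources, hosts and untouched barcodes partition the originals
  expect_length(intersect(db$plan$host, db$plan$source), 0)
  expect_setequal(c(db$counts$barcodes, db$plan$source),
                  pool$counts$barcodes)
  # additivity at every SNP for each merged barcode
  A0 <- as.matrix(pool$counts$AD); D0 <- as.matrix(pool$counts$DP)
  A1 <- as.matrix(db$counts$AD); D1 <- as.matrix(db$counts$DP)
  rownames(A0) <- rownames(D0) <- pool$counts$barcodes
  rownames(A1) <- rownames(D1) <- db$counts$barcodes
  for (i in seq_len(nrow(db$plan))) {
    h <- db$plan$host[i]; s <- db$plan$source[i]
    expect_equal(A1[h, ], A0[h, ] + A0[s, ])
    expect_equal(D1[h, ], D0[h, ] + D0[s, ])
  }
  # global conservation
  expect_equal(sum(A1), sum(A0))
  expect_equal(sum(D1), sum(D0))
  # unordered donor pair recorded
  tr <- db$truth[match(db$plan$host, db$truth$barcode), ]
  expect_true(all(tr$donor_a <= tr$donor_b))
  expect_true(all(tr$donor_a == pmin(db$plan$host_donor,
                                     db$plan$source_donor)))
})

test_that("same-donor doublet fraction matches the mixture proportions", {
  # donors at proportions w: expected same-donor pair fraction ~ sum(w^2)
  w <- c(0.5, 0.3, 0.2); n <- 4000
  cells <- round(w * n)
  truth <- cell_truth(sprintf("BC%05d", seq_len(n)), "singlet",
                      rep(1:3, cells))
  counts <- allele_counts(truth$barcode,
                          Matrix::Matrix(0, n, 4, sparse = TRUE),
                          Matrix::Matrix(1, n, 4, sparse = TRUE))
  db <- simulate_doublets(counts, truth, 0.3, seed = 31)
  obs <- mean(db$plan$host_donor == db$plan$source_donor)
  # Monte-Carlo pairing oracle, independent of the implementation
  donors <- rep(1:3, cells)
  mc <- replicate(300, {
    pick <- sample(n, 2 * nrow(db$plan))
    a <- donors[pick[seq_len(nrow(db$plan))]]
    b <- donors[pick[nrow(db$plan) + seq_len(nrow(db$plan))]]
    mean(a == b)
  })
  expect_lt(abs(mean(mc) - sum(w^2)), 0.02)  # oracle sanity
  expect_lt(abs(obs - sum(w^2)), 4 * sd(mc) + 1e-9)
})

test_that("debris redistribution conserves reads and is uniform", {
  pool <- toy_pool(K = 2, cells = 25, V = 60, seed = 23)
  # null case is the identity
  de0 <- simulate_debris(pool$counts, pool$truth, 0, seed = 1)
  expect_identical(de0$counts, pool$counts)
  expect_identical(de0$truth, pool$truth)

  de <- simulate_debris(pool$counts, pool$truth, 0.2, seed = 2)
  expect_equal(nrow(de$plan), round(0.2 * 50))
  expect_equal(sum(de$counts$AD), sum(pool$counts$AD))
  expect_equal(sum(de$counts$DP), sum(pool$counts$DP))
  expect_setequal(c(de$counts$barcodes, de$plan$barcode),
                  pool$counts$barcodes)
  expect_true(all(de$truth$label_type[match(de$plan$barcode,
                                            de$truth$barcode)] == "debris"))
  expect_error(simulate_debris(pool$counts, pool$truth, 0.999), "surviving")
})

test_that("scattered debris reads are uniform over survivors", {
  # 11 identical barcodes; whichever becomes debris sheds 10,000 reads
  # over the 10 survivors
  n <- 11; V <- 100
  DP <- Matrix::Matrix(100, n, V, sparse = TRUE)  # 10,000 reads each
  AD <- Matrix::Matrix(0, n, V, sparse = TRUE)
  truth <- cell_truth(sprintf("B%02d", 1:n), "singlet", rep(1L, n))
  counts <- allele_counts(truth$barcode, AD, DP)
  de <- simulate_debris(counts, truth, 1 / n, seed = 7)
  received <- Matrix::rowSums(de$counts$DP) - V * 100
  expect_equal(sum(received), 10000)
  fit <- chisq.test(received, p = rep(1 / 10, 10))
  expect_gt(fit$p.value, 0.01)
})

test_that("wholesale debris mode moves each debris barcode to one recipient", {
  pool <- toy_pool(K = 2, cells = 10, V = 40, seed = 29)
  de <- simulate_debris(pool$counts, pool$truth, 0.1, seed = 3,
                        mode = "wholesale")
  expect_equal(sum(de$counts$DP), sum(pool$counts$DP))
  # exactly one survivor's depth changed (2 debris of 20 -> 2 recipients max)
  old <- Matrix::rowSums(pool$counts$DP)[match(de$counts$barcodes,
                                               pool$counts$barcodes)]
  changed <- sum(Matrix::rowSums(de$counts$DP) != old)
  expect_lte(changed, nrow(de$plan))
  expect_gte(changed, 1)
})
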