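#' Demultiplexing configuration
#'
#' @param error_rate Sequencing error rate epsilon used in the genotype-
#'   aware binomial read model.
#' @param doublet_prior Prior probability delta that a barcode is a
#'   distinct-donor doublet, in [0, 1).
#' @param assign_threshold Posterior threshold tau in (0.5, 1]: the argmax
#'   class is called only if its posterior reaches tau, otherwise the
#'   barcode is unassigned. tau > 0.5 guarantees at most one class can
#'   clear the threshold.
#' @param K Number of donors to infer (genotype-free mode).
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   penalized log-likelihood improvement.
#' @param n_init Number of random EM restarts; the best objective wins.
#' @param alpha,beta Beta(alpha, beta) smoothing pseudo-counts on inferred
#'   allele fractions (MAP-EM); both > 1 keeps theta off the boundary.
#' @param seed Integer seed (genotype-free initialization).
#' @return Object of class `demux_config`.
#' @export
demux_config <- function(error_rate = 0.001, doublet_prior = 0.05,
                         assign_threshold = 0.9, K = NULL,
                         max_iter = 100L, tol = 1e-6, n_init = 3L,
                         alpha = 1.5, beta = 1.5, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.5,
            doublet_prior >= 0, doublet_prior < 1,
            assign_threshold > 0.5, assign_threshold <= 1,
            max_iter >= 1, tol > 0, n_init >= 1, alpha > 0, beta > 0)
  structure(list(error_rate = error_rate, doublet_prior = doublet_prior,
                 assign_threshold = assign_threshold, K = K,
                 max_iter = as.integer(max_iter), tol = tol,
                 n_init = as.integer(n_init), alpha = alpha, beta = beta,
                 seed = as.integer(seed)),
            class = "demux_config")
}

#' Singlet log-likelihood of a barcode's allele counts under a genotype
#'
#' Sum over sites with non-missing genotype and positive depth of
#' log Binomial(a | d, pi), pi = phi + eps(1 - 2 phi), phi = g/2. Missing
#' genotypes contribute nothing (site skipped, not imputed); an empty sum
#' is 0.
#'
#' @param a,d Integer vectors of ALT counts and depths (a <= d).
#' @param g Genotype vector in \{0,1,2,NA\}.
#' @param error_rate Sequencing error rate.
#' @return Log-likelihood (scalar).
#' @export
singlet_loglik <- function(a, d, g, error_rate) {
  stopifnot(length(a) == length(d), length(g) == length(d))
  if (any(a > d)) stop("ALT count exceeds depth")
  keep <- !is.na(g) & d > 0
  if (!any(keep)) return(0)
  pi <- clamp_prob(alt_prob(g[keep] / 2, error_rate))
  sum(stats::dbinom(a[keep], d[keep], pi, log = TRUE))
}

#' Doublet log-likelihood under an equal-mixture two-genotype model
#'
#' As [singlet_loglik()] but with pi = (pi_i + pi_j)/2, the read model for
#' a droplet containing one cell of each donor at equal mixing; sites where
#' either genotype is missing are skipped.
#'
#' @param a,d Integer count vectors.
#' @param g_i,g_j Genotype vectors of the two donors.
#' @param error_rate Sequencing error rate.
#' @return Log-likelihood (scalar).
#' @export
doublet_loglik <- function(a, d, g_i, g_j, error_rate) {
  stopifnot(length(a) == length(d), length(g_i) == length(d),
            length(g_j) == length(d))
  if (any(a > d)) stop("ALT count exceeds depth")
  keep <- !is.na(g_i) & !is.na(g_j) & d > 0
  if (!any(keep)) return(0)
  pi <- (alt_prob(g_i[keep] / 2, error_rate) +
           alt_prob(g_j[keep] / 2, error_rate)) / 2
  sum(stats::dbinom(a[keep], d[keep], clamp_prob(pi), log = TRUE))
}

# Score every barcode against a list of per-class ALT-probability vectors.
# classes: list of list(pi = numeric(V), mask = logical(V)); masked-out
# sites contribute zero log-likelihood. Returns the C x n_class
# log-likelihood matrix including the binomial coefficient term (constant
# per barcode across classes).
score_classes <- function(AD, DP, classes) {
  C <- nrow(AD)
  L <- matrix(0, C, length(classes))
  # log C(d, a) in the sparsity pattern of DP; summed per class over that
  # class's masked-in sites (a site with missing genotype contributes
  # nothing, coefficient included)
  Ts <- methods::as(DP, "TsparseMatrix")
  LC <- if (length(Ts@x)) {
    av <- AD[cbind(Ts@i + 1L, Ts@j + 1L)]
    Matrix::sparseMatrix(i = Ts@i + 1L, j = Ts@j + 1L,
                         x = lchoose(Ts@x, av), dims = dim(DP))
  } else DP
  for (j in seq_along(classes)) {
    pi <- clamp_prob(classes[[j]]$pi)
    m <- classes[[j]]$mask
    x1 <- ifelse(m, log(pi) - log1p(-pi), 0)
    x2 <- ifelse(m, log1p(-pi), 0)
    L[, j] <- as.numeric(AD %*% x1 + DP %*% x2 + LC %*% as.numeric(m))
  }
  L
}

# Posterior assignment shared by both demultiplexers.
# class_type: "singlet"/"doublet" per column of L; priors sum to 1.
assign_from_loglik <- function(barcodes, L, class_type, class_donor_a,
                               class_donor_b, donor_ids, priors, tau) {
  lp <- sweep(L, 2L, log(priors), "+")
  post <- exp(lp - row_logsumexp(lp))
  post <- post / rowSums(post)
  best <- max.col(post, ties.method = "first")  # ties -> lowest class index
  max_post <- post[cbind(seq_len(nrow(post)), best)]
  call <- ifelse(max_post >= tau,
                 ifelse(class_type[best] == "singlet", "singlet", "doublet"),
                 "unassigned")
  donor_a <- ifelse(call == "unassigned", NA_integer_, class_donor_a[best])
  donor_b <- ifelse(call == "doublet", class_donor_b[best], NA_integer_)
  res <- data.frame(
    barcode = barcodes, call = call,
    donor = ifelse(call == "singlet", donor_ids[donor_a], NA_character_),
    donor_a = donor_a, donor_b = donor_b, max_posterior = max_post,
    stringsAsFactors = FALSE)
  class(res) <- c("demux_result", "data.frame")
  attr(res, "posterior") <- post
  attr(res, "class_type") <- class_type
  attr(res, "donor_ids") <- donor_ids
  res
}

# Build the singlet + distinct-pair doublet class list from a K x V matrix
# of per-donor ALT probabilities (NA = site unusable for that donor).
build_classes <- function(Pi) {
  K <- nrow(Pi)
  classes <- list(); type <- character(0); da <- integer(0); db <- integer(0)
  for (k in seq_len(K)) {
    classes[[length(classes) + 1L]] <-
      list(pi = ifelse(is.na(Pi[k, ]), 0.5, Pi[k, ]), mask = !is.na(Pi[k, ]))
    type <- c(type, "singlet"); da <- c(da, k); db <- c(db, NA_integer_)
  }
  if (K >= 2) {
    for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
      pi <- (Pi[i, ] + Pi[j, ]) / 2
      classes[[length(classes) + 1L]] <-
        list(pi = ifelse(is.na(pi), 0.5, pi), mask = !is.na(pi))
      type <- c(type, "doublet"); da <- c(da, i); db <- c(db, j)
    }
  }
  list(classes = classes, type = type, donor_a = da, donor_b = db)
}

class_priors <- function(K, delta) {
  n_pairs <- K * (K - 1L) / 2L
  if (n_pairs == 0) delta <- 0
  c(rep((1 - delta) / K, K),
    if (n_pairs > 0) rep(delta / n_pairs, n_pairs))
}

#' Genotype-aware demultiplexing by posterior donor assignment
#'
#' Scores every barcode against K singlet classes and K(K-1)/2
#' distinct-donor doublet classes under the binomial read model, with
#' priors (1-delta)/K per singlet class and delta/#pairs per doublet
#' class. The argmax class is called when its posterior reaches the
#' threshold tau; otherwise the barcode is unassigned.
#'
#' @param counts An [allele_counts()].
#' @param panel The [snp_panel()] matching `counts` columns.
#' @param reference A [donor_genotypes()] reference (missing entries
#'   allowed; sites absent from `ref_panel` are skipped).
#' @param ref_panel The panel matching `reference` columns; NULL means the
#'   reference is already aligned to `panel`.
#' @param config A [demux_config()].
#' @return A `demux_result` data frame (one row per barcode) with the
#'   posterior matrix attached as attribute `"posterior"`.
#' @export
demux_with_genotypes <- function(counts, panel, reference, ref_panel = NULL,
                                 config = demux_config()) {
  validate_allele_counts(counts); validate_donor_genotypes(reference)
  validate_snp_panel(panel)
  K <- nrow(reference$G)
  if (K < 2 && config$doublet_prior > 0)
    stop("doublet prior requires at least 2 donors")
  if (is.null(ref_panel)) {
    if (ncol(reference$G) != nrow(panel))
      stop("reference not aligned to the count panel; supply ref_panel")
    G <- reference$G
  } else {
    validate_snp_panel(ref_panel)
    idx <- match(panel_key(panel), panel_key(ref_panel))
    G <- matrix(NA_integer_, K, nrow(panel))
    hit <- !is.na(idx)
    G[, hit] <- reference$G[, idx[hit], drop = FALSE]
  }
  Pi <- alt_prob(G / 2, config$error_rate)  # NA propagates for missing g
  cl <- build_classes(Pi)
  L <- score_classes(counts$AD, counts$DP, cl$classes)
  assign_from_loglik(counts$barcodes, L, cl$type, cl$donor_a, cl$donor_b,
                     reference$donor_ids,
                     class_priors(K, config$doublet_prior),
                     config$assign_threshold)
}

#' Genotype-free demultiplexing by EM over donor allele fractions
#'
#' Infers a K x V matrix theta of donor ALT fractions by MAP-EM on the
#' singlet binomial mixture (Beta(alpha, beta) smoothing on theta), keeping
#' the best of `n_init` random restarts. After convergence, distinct-pair
#' doublet classes are built from the converged theta ((theta_i+theta_j)/2)
#' and every barcode is re-scored with the same prior/threshold rule as
#' [demux_with_genotypes()]. Inferred donor labels are arbitrary; use
#' [match_donor_labels()] against truth or an external reference.
#'
#' @param counts An [allele_counts()].
#' @param sites The sites-only [snp_panel()] (defines the columns used).
#' @param config A [demux_config()] with `K` set.
#' @return List with `result` (a `demux_result`) and `model` (class
#'   `inferred_model`: `theta`, per-restart penalized log-likelihood
#'   `trace`, `chosen_init`, final `loglik`).
#' @export
demux_genotype_free <- function(counts, sites, config) {
  validate_allele_counts(counts)
  K <- config$K
  stopifnot(!is.null(K), K >= 1)
  C <- nrow(counts$AD)
  if (K > C) stop("cannot infer more donors than barcodes")
  site_idx <- seq_len(ncol(counts$AD))
  if (!is.null(sites)) {
    validate_snp_panel(sites)
    site_idx <- attr(sites, "site_index")
    if (is.null(site_idx)) {
      stopifnot(nrow(sites) == ncol(counts$AD))
      site_idx <- seq_len(ncol(counts$AD))
    }
  }
  AD <- counts$AD[, site_idx, drop = FALSE]
  DP <- counts$DP[, site_idx, drop = FALSE]
  V <- ncol(AD)
  a0 <- config$alpha - 1; b0 <- config$beta - 1

  # constant binomial coefficient term
  Ts <- methods::as(DP, "TsparseMatrix")
  lc_total <- if (length(Ts@x))
    sum(lchoose(Ts@x, AD[cbind(Ts@i + 1L, Ts@j + 1L)])) else 0

  em_once <- function(init_seed) {
    assign0 <- with_rng(init_seed, sample.int(K, C, replace = TRUE))
    R <- matrix(0, C, K); R[cbind(seq_len(C), assign0)] <- 1
    theta <- NULL; trace <- numeric(0); prev <- -Inf
    for (it in seq_len(config$max_iter)) {
      # M-step (uses current responsibilities)
      num <- a0 + as.matrix(Matrix::t(Matrix::crossprod(AD, R)))  # K x V
      den <- a0 + b0 + as.matrix(Matrix::t(Matrix::crossprod(DP, R)))
      theta <- clamp_prob(num / pmax(den, .Machine$double.eps))
      # E-step
      L <- as.matrix(AD %*% t(log(theta) - log1p(-theta)) +
                       DP %*% t(log1p(-theta)))
      lse <- row_logsumexp(L - log(K))
      obj <- sum(lse) + lc_total +
        sum(a0 * log(theta) + b0 * log1p(-theta))
      R <- exp(L - log(K) - lse); R <- R / rowSums(R)
      trace <- c(trace, obj)
      if (obj - prev < config$tol && it > 1) break
      prev <- obj
    }
    list(theta = theta, trace = trace, obj = trace[length(trace)])
  }

  runs <- lapply(seq_len(config$n_init), function(r)
    em_once(derive_seed(config$seed, paste0("em_init_", r))))
  best <- which.max(vapply(runs, `[[`, numeric(1), "obj"))
  theta <- runs[[best]]$theta

  Pi_full <- matrix(NA_real_, K, ncol(counts$AD))
  Pi_full[, site_idx] <- theta
  cl <- build_classes(Pi_full)
  L <- score_classes(counts$AD, counts$DP, cl$classes)
  res <- assign_from_loglik(counts$barcodes, L, cl$type, cl$donor_a,
                            cl$donor_b, paste0("inferred", seq_len(K)),
                            class_priors(K, config$doublet_prior),
                            config$assign_threshold)
  model <- structure(list(theta = theta, site_index = site_idx,
                          trace = runs[[best]]$trace, chosen_init = best,
                          traces = lapply(runs, `[[`, "trace"),
                          loglik = runs[[best]]$obj),
                     class = "inferred_model")
  list(result = res, model = model)
}
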