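#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Each stochastic operation in the package draws from its own substream,
#' keyed by a master seed plus a string label. Adding or reordering stages
#' therefore never perturbs the draws of other stages.
#'
#' @param seed Integer master seed.
#' @param label Character scalar naming the substream.
#' @return An integer seed in `[1, 2147483562]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  bytes <- utf8ToInt(paste0(format(seed, scientific = FALSE), ":", label))
  h <- 11
  # multiplicative hash; products stay < 2^53 so arithmetic is exact
  for (b in bytes) h <- (h * 69069 + b) %% 2147483647
  as.integer(h %% 2147483562) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Uniform distribution specification
#'
#' Small declarative container used for the minor-allele-frequency law and
#' the somatic clone-fraction law.
#'
#' @param min,max Bounds, `min < max`.
#' @return An object of class `dist_spec`.
#' @export
dist_uniform <- function(min, max) {
  stopifnot(is.numeric(min), is.numeric(max), length(min) == 1L,
            length(max) == 1L, min < max)
  structure(list(kind = "uniform", min = min, max = max), class = "dist_spec")
}

draw_dist <- function(law, n) {
  stopifnot(inherits(law, "dist_spec"))
  switch(law$kind,
    uniform = stats::runif(n, law$min, law$max),
    stop("unknown distribution kind: ", law$kind)
  )
}

# Validate that a dist_spec stays within [lo, hi]; used to reject MAF laws
# outside (0, 0.5].
check_dist_bounds <- function(law, lo, hi, what) {
  if (law$min <= lo || law$max > hi) {
    stop(sprintf("%s must have support within (%g, %g]; got [%g, %g]",
                 what, lo, hi, law$min, law$max))
  }
  invisible(law)
}

# ALT-read emission probability under sequencing error rate eps:
# a true-ALT read is miscalled with prob eps and vice versa.
alt_prob <- function(phi, eps) phi + eps * (1 - 2 * phi)

clamp_prob <- function(p, floor = 1e-12) pmin(pmax(p, floor), 1 - floor)

# round-half-away-from-zero (base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Generate unique 10x-style cell barcodes
#'
#' @param n Number of barcodes.
#' @param seed Integer seed.
#' @param width Barcode length in bases.
#' @return Character vector of `n` distinct barcodes over \{A,C,G,T\}.
#' @export
make_barcodes <- function(n, seed, width = 16L) {
  stopifnot(n >= 0)
  if (n == 0) return(character(0))
  with_rng(seed, {
    out <- character(0)
    while (length(out) < n) {
      need <- n - length(out)
      m <- matrix(sample(c("A", "C", "G", "T"), (need + 8L) * width,
                         replace = TRUE), ncol = width)
      out <- unique(c(out, apply(m, 1L, paste0, collapse = "")))
    }
    out[seq_len(n)]
  })
}

# lexicographic permutations of 1..k as a matrix (k! rows); k is small
# (donor counts), guarded at 8.
all_permutations <- function(k) {
  stopifnot(k >= 1, k <= 8)
  if (k == 1) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  r <- 0L
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    block <- matrix(rest[sub], nrow = nrow(sub))
    idx <- r + seq_len(nrow(sub))
    out[idx, 1L] <- first
    out[idx, -1L] <- block
    r <- r + nrow(sub)
  }
  out
}

# row-wise log-sum-exp for a dense matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}
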