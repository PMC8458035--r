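#' Number of merges needed to hit a target doublet fraction
#'
#' Merging d barcode pairs out of N original barcodes leaves N - d final
#' barcodes of which d are doublets; the planner returns the d whose final
#' doublet fraction d/(N - d) is closest to the target p, breaking ties
#' toward the smaller d. E.g. 15,202 original barcodes at a 30% target give
#' 3,508 merges and 11,694 final barcodes.
#'
#' @param N Number of original barcodes.
#' @param p Target doublet fraction among final barcodes, in [0, 1).
#' @return Integer number of merged (doublet) barcodes.
#' @export
n_doublets_for_target <- function(N, p) {
  stopifnot(N >= 1, p >= 0)
  if (p >= 1) stop("target doublet fraction must be < 1")
  if (p == 0) return(0L)
  if (N < 2) stop("need N >= 2 to form a doublet")
  # d/(N-d) is strictly increasing in d, so the minimizer of |d/(N-d) - p|
  # is a rounding of the real solution d = pN/(1+p)
  d0 <- p * N / (1 + p)
  cand <- unique(pmin(pmax(c(floor(d0), ceiling(d0)), 0L), N - 1L))
  obj <- abs(cand / (N - cand) - p)
  cand <- cand[order(obj, cand)]  # ties -> smaller d
  as.integer(cand[1])
}

#' Simulate doublets by merging random pairs of cell barcodes
#'
#' Draws d source and d host barcodes (disjoint, uniformly without
#' replacement), adds each source's ALT and depth vectors onto its host,
#' deletes the source barcodes, and relabels each host as an unordered
#' doublet of the two donors (same-donor pairs are allowed and recorded:
#' they are non-identifiable from germline SNPs).
#'
#' @param counts An [allele_counts()] of singlet cells.
#' @param truth The matching [cell_truth()] (all singlets).
#' @param p Target doublet fraction among final barcodes, in [0, 1).
#' @param seed Integer seed.
#' @return List with `counts`, `truth` and `plan` (a data frame with one
#'   row per merge: host, source, host donor, source donor).
#' @export
simulate_doublets <- function(counts, truth, p, seed = 1L) {
  validate_allele_counts(counts)
  stopifnot(identical(counts$barcodes, truth$barcode))
  if (!all(truth$label_type == "singlet"))
    stop("doublet simulation expects a singlet pool")
  N <- length(counts$barcodes)
  d <- n_doublets_for_target(N, p)
  plan <- data.frame(host = character(0), source = character(0),
                     host_donor = integer(0), source_donor = integer(0),
                     stringsAsFactors = FALSE)
  if (d == 0) return(list(counts = counts, truth = truth, plan = plan))
  if (2 * d > N)
    stop("cannot draw ", d, " disjoint source/host pairs from ", N,
         " barcodes")
  with_rng(seed, {
    pick <- sample.int(N, 2L * d)
    src <- pick[seq_len(d)]
    host <- pick[d + seq_len(d)]
    AD <- counts$AD; DP <- counts$DP
    AD[host, ] <- AD[host, , drop = FALSE] + AD[src, , drop = FALSE]
    DP[host, ] <- DP[host, , drop = FALSE] + DP[src, , drop = FALSE]
    keep <- setdiff(seq_len(N), src)
    new_counts <- allele_counts(counts$barcodes[keep],
                                AD[keep, , drop = FALSE],
                                DP[keep, , drop = FALSE])
    merge_somatic <- function(a, b) {
      s <- union(strsplit(a, ";")[[1]], strsplit(b, ";")[[1]])
      paste(sort(as.integer(s[nzchar(s)])), collapse = ";")
    }
    new_truth <- truth
    new_truth$label_type[host] <- "doublet"
    new_truth$donor_b[host] <- truth$donor_a[src]
    new_truth$somatic_sites[host] <- mapply(
      merge_somatic, truth$somatic_sites[host], truth$somatic_sites[src])
    new_truth <- cell_truth(new_truth$barcode[keep],
                            new_truth$label_type[keep],
                            new_truth$donor_a[keep],
                            new_truth$donor_b[keep],
                            new_truth$somatic_sites[keep])
    plan <- data.frame(host = counts$barcodes[host],
                       source = counts$barcodes[src],
                       host_donor = truth$donor_a[host],
                       source_donor = truth$donor_a[src],
                       stringsAsFactors = FALSE)
    list(counts = new_counts, truth = new_truth, plan = plan)
  })
}

#' Redistribute reads of debris barcodes to emulate ambient RNA
#'
#' Selects round(f x N) barcodes (doublet barcodes are eligible), removes
#' them from the matrix, and reassigns each of their reads uniformly at
#' random among the surviving barcodes. In `"scatter"` mode (default) reads
#' are scattered independently, realized as a multinomial split of the
#' debris ALT and REF counts per site across survivors; in `"wholesale"`
#' mode each debris barcode's counts go to a single random survivor.
#'
#' @param counts An [allele_counts()].
#' @param truth The matching [cell_truth()].
#' @param f Fraction of barcodes turned into debris, in [0, 1).
#' @param seed Integer seed.
#' @param mode `"scatter"` or `"wholesale"`.
#' @return List with `counts`, `truth` (debris rows relabelled
#'   `"debris"` and kept for provenance) and `plan`.
#' @export
simulate_debris <- function(counts, truth, f, seed = 1L,
                            mode = c("scatter", "wholesale")) {
  mode <- match.arg(mode)
  validate_allele_counts(counts)
  stopifnot(identical(counts$barcodes, truth$barcode), f >= 0, f < 1)
  N <- length(counts$barcodes)
  n_deb <- as.integer(round_half_away(f * N))
  plan <- data.frame(barcode = character(0), role = character(0),
                     stringsAsFactors = FALSE)
  if (n_deb == 0) return(list(counts = counts, truth = truth, plan = plan))
  if (n_deb >= N) stop("debris fraction leaves no surviving barcodes")
  with_rng(seed, {
    deb <- sample.int(N, n_deb)
    surv <- setdiff(seq_len(N), deb)
    AD <- counts$AD; DP <- counts$DP
    if (mode == "scatter") {
      # reads are i.i.d. uniform over survivors, so debris reads can be
      # pooled per site before the multinomial split
      alt_tot <- Matrix::colSums(AD[deb, , drop = FALSE])
      ref_tot <- Matrix::colSums(DP[deb, , drop = FALSE]) - alt_tot
      ns <- length(surv)
      add_alt <- matrix(0, ns, ncol(AD))
      add_ref <- matrix(0, ns, ncol(AD))
      for (v in which(alt_tot > 0))
        add_alt[, v] <- stats::rmultinom(1L, alt_tot[v], rep(1, ns))
      for (v in which(ref_tot > 0))
        add_ref[, v] <- stats::rmultinom(1L, ref_tot[v], rep(1, ns))
      AD_new <- AD[surv, , drop = FALSE] + add_alt
      DP_new <- DP[surv, , drop = FALSE] + add_alt + add_ref
    } else {
      recipient <- sample(surv, n_deb, replace = TRUE)
      AD_new <- AD[surv, , drop = FALSE]
      DP_new <- DP[surv, , drop = FALSE]
      surv_pos <- match(recipient, surv)
      for (i in seq_len(n_deb)) {
        AD_new[surv_pos[i], ] <- AD_new[surv_pos[i], ] + AD[deb[i], ]
        DP_new[surv_pos[i], ] <- DP_new[surv_pos[i], ] + DP[deb[i], ]
      }
    }
    new_counts <- allele_counts(counts$barcodes[surv], AD_new, DP_new)
    new_truth <- truth
    new_truth$label_type[deb] <- "debris"
    class(new_truth) <- class(truth)
    plan <- data.frame(barcode = counts$barcodes[deb], role = "debris",
                       stringsAsFactors = FALSE)
    attr(plan, "mode") <- mode
    list(counts = new_counts, truth = new_truth, plan = plan)
  })
}
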