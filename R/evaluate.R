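#' Match arbitrary inferred donor labels to true donors
#'
#' Genotype-free demultiplexing infers donors up to permutation. This
#' finds the permutation of inferred labels maximizing the number of true
#' singlets assigned to their own donor (optimal bipartite assignment,
#' solved exactly by exhaustive search over the K! permutations with a
#' deterministic lexicographic tie-break; K is small).
#'
#' @param result A `demux_result`.
#' @param truth The matching [cell_truth()].
#' @param K_true Number of true donors (default: max donor index in truth).
#' @return Integer vector `perm` with `perm[i]` the true donor matched to
#'   inferred donor `i`.
#' @export
match_donor_labels <- function(result, truth, K_true = NULL) {
  donor_ids <- attr(result, "donor_ids")
  K_inf <- length(donor_ids)
  if (is.null(K_true))
    K_true <- max(truth$donor_a, truth$donor_b, na.rm = TRUE)
  if (K_inf != K_true)
    stop("label matching requires equal numbers of inferred and true donors")
  tt <- truth[truth$label_type == "singlet", , drop = FALSE]
  res <- result[match(tt$barcode, result$barcode), , drop = FALSE]
  M <- matrix(0L, K_inf, K_true)
  sing <- !is.na(res$donor_a) & res$call == "singlet"
  if (any(sing)) {
    tab <- table(factor(res$donor_a[sing], levels = seq_len(K_inf)),
                 factor(tt$donor_a[sing], levels = seq_len(K_true)))
    M <- matrix(as.integer(tab), K_inf, K_true)
  }
  perms <- all_permutations(K_inf)
  scores <- apply(perms, 1L, function(p) sum(M[cbind(seq_len(K_inf), p)]))
  perms[which.max(scores), ]  # first max = lexicographically smallest
}

#' Relabel a demultiplexing result through a donor permutation
#'
#' @param result A `demux_result`.
#' @param mapping Integer permutation from [match_donor_labels()].
#' @param donor_ids Optional true donor labels for the `donor` column.
#' @return The relabelled `demux_result`.
#' @export
apply_donor_mapping <- function(result, mapping, donor_ids = NULL) {
  stopifnot(length(mapping) == length(attr(result, "donor_ids")),
            identical(sort(mapping), seq_along(mapping)))
  if (is.null(donor_ids)) donor_ids <- paste0("donor", seq_along(mapping))
  out <- result
  out$donor_a <- ifelse(is.na(result$donor_a), NA_integer_,
                        mapping[result$donor_a])
  out$donor_b <- ifelse(is.na(result$donor_b), NA_integer_,
                        mapping[result$donor_b])
  swap <- !is.na(out$donor_b) & out$donor_b < out$donor_a
  tmp <- out$donor_a[swap]
  out$donor_a[swap] <- out$donor_b[swap]; out$donor_b[swap] <- tmp
  out$donor <- ifelse(out$call == "singlet", donor_ids[out$donor_a],
                      NA_character_)
  attr(out, "donor_ids") <- donor_ids
  attr(out, "posterior") <- attr(result, "posterior")
  attr(out, "mapping") <- mapping
  out
}

# shared preamble: drop debris rows, align result to truth, reject unknowns
align_result_truth <- function(result, truth) {
  tt <- truth[truth$label_type != "debris", , drop = FALSE]
  if (!all(result$barcode %in% tt$barcode))
    stop("result contains barcodes absent from truth")
  res <- result[match(tt$barcode, result$barcode), , drop = FALSE]
  list(truth = tt, result = res)
}

#' Per-sample demultiplexing precision and recall
#'
#' Recall for sample s: the proportion of true singlet cells of s that are
#' called singlet and assigned to s. Precision for sample s: the
#' proportion of all barcodes called singlet-s that are true singlets of
#' s (so same-donor doublets assigned to their own donor reduce
#' precision: they are identified cells but not true singlets). Debris
#' barcodes are excluded throughout. Zero denominators give `NA`.
#'
#' @param result A `demux_result` (relabelled if genotype-free).
#' @param truth The matching [cell_truth()].
#' @param K Number of donors (default from truth).
#' @return Data frame: sample, n_true_singlets, n_called, precision, recall.
#' @export
precision_recall <- function(result, truth, K = NULL) {
  al <- align_result_truth(result, truth)
  tt <- al$truth; res <- al$result
  if (is.null(K)) K <- max(tt$donor_a, tt$donor_b, na.rm = TRUE)
  out <- lapply(seq_len(K), function(s) {
    true_s <- tt$label_type == "singlet" & tt$donor_a == s
    called_s <- res$call == "singlet" & !is.na(res$donor_a) &
      res$donor_a == s
    tp <- sum(true_s & called_s)
    data.frame(sample = paste0("donor", s),
               n_true_singlets = sum(true_s), n_called = sum(called_s),
               precision = if (sum(called_s) > 0) tp / sum(called_s)
                           else NA_real_,
               recall = if (sum(true_s) > 0) tp / sum(true_s)
                        else NA_real_)
  })
  do.call(rbind, out)
}

#' Confusion table of true categories versus demultiplexing calls
#'
#' Rows are the true categories: one singlet row per sample, one
#' same-donor (non-identifiable) doublet row per sample, and one row per
#' distinct-donor (identifiable) doublet pair. Columns are the calls: one
#' per donor, plus `doublet` and `unassigned`.
#'
#' @param result A `demux_result`.
#' @param truth The matching [cell_truth()].
#' @param K Number of donors (default from truth).
#' @return Integer matrix with named rows and columns.
#' @export
confusion_matrix <- function(result, truth, K = NULL) {
  al <- align_result_truth(result, truth)
  tt <- al$truth; res <- al$result
  if (is.null(K)) K <- max(tt$donor_a, tt$donor_b, na.rm = TRUE)
  true_cat <- ifelse(
    tt$label_type == "singlet", paste0("singlet:donor", tt$donor_a),
    ifelse(tt$donor_a == tt$donor_b,
           paste0("doublet:donor", tt$donor_a, "-donor", tt$donor_a),
           paste0("doublet:donor", tt$donor_a, "-donor", tt$donor_b)))
  call_cat <- ifelse(res$call == "singlet", paste0("donor", res$donor_a),
                     res$call)
  row_levels <- c(paste0("singlet:donor", seq_len(K)),
                  paste0("doublet:donor", seq_len(K), "-donor", seq_len(K)))
  if (K >= 2) {
    for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K))
      row_levels <- c(row_levels, paste0("doublet:donor", i, "-donor", j))
  }
  col_levels <- c(paste0("donor", seq_len(K)), "doublet", "unassigned")
  tab <- table(factor(true_cat, levels = row_levels),
               factor(call_cat, levels = col_levels))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Purity of doublet calls
#'
#' The fraction of barcodes called doublet that are true identifiable
#' (distinct-donor) doublets. `NA` when no barcode is called doublet.
#'
#' @param result A `demux_result`.
#' @param truth The matching [cell_truth()].
#' @return Fraction in [0, 1], or `NA`.
#' @export
doublet_call_purity <- function(result, truth) {
  al <- align_result_truth(result, truth)
  tt <- al$truth; res <- al$result
  called <- res$call == "doublet"
  if (!any(called)) return(NA_real_)
  true_ident <- tt$label_type == "doublet" & tt$donor_a != tt$donor_b
  sum(called & true_ident) / sum(called)
}

#' Full evaluation report
#'
#' Bundles per-sample precision/recall, the confusion table and the
#' doublet-call purity. When `match_labels` is TRUE (genotype-free runs)
#' the donor permutation is first recovered with [match_donor_labels()].
#'
#' @param result A `demux_result`.
#' @param truth The matching [cell_truth()].
#' @param match_labels Recover the donor permutation before scoring?
#' @return List of class `eval_report`: `metrics`, `confusion`, `purity`,
#'   `mapping`, `result`.
#' @export
eval_report <- function(result, truth, match_labels = FALSE) {
  mapping <- seq_along(attr(result, "donor_ids"))
  if (match_labels) {
    mapping <- match_donor_labels(result, truth)
    result <- apply_donor_mapping(result, mapping)
  }
  structure(list(metrics = precision_recall(result, truth),
                 confusion = confusion_matrix(result, truth),
                 purity = doublet_call_purity(result, truth),
                 mapping = mapping, result = result),
            class = "eval_report")
}
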