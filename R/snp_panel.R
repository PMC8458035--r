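#' SNP panel objects
#'
#' A SNP panel is a data frame with one row per biallelic variant site and
#' columns `chrom`, `pos` (1-based), `ref`, `alt`, `maf` (population minor
#' allele frequency in (0, 0.5]), `region_tag` (`"three_prime_utr"` or
#' `"other"`) and `origin` (`"germline"` or `"somatic"`). Somatic sites are
#' donor-private and carry `maf = NA` since they are not population variants.
#'
#' @param df Data frame with the columns above.
#' @return `df` with class `snp_panel`, validated.
#' @export
snp_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$origin)) df$origin <- rep("germline", nrow(df))
  rownames(df) <- NULL
  class(df) <- c("snp_panel", "data.frame")
  validate_snp_panel(df)
  df
}

panel_key <- function(panel) {
  paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":")
}

# canonical sort order: chromosome (numeric where possible), then position
panel_order <- function(chrom, pos) {
  num <- suppressWarnings(as.integer(chrom))
  order(is.na(num), num, chrom, pos)
}

validate_snp_panel <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  req <- c("chrom", "pos", "ref", "alt", "maf", "region_tag", "origin")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols))
    stop("snp_panel missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(panel) == 0) return(invisible(panel))
  if (anyDuplicated(panel_key(panel)))
    stop("snp_panel has duplicated (chrom, pos, ref, alt) records")
  germ <- panel$origin == "germline"
  if (any(is.na(panel$maf[germ])) ||
      any(panel$maf[germ] <= 0 | panel$maf[germ] > 0.5))
    stop("germline MAFs must lie strictly in (0, 0.5]")
  if (!all(panel$region_tag %in% c("three_prime_utr", "other")))
    stop("region_tag must be 'three_prime_utr' or 'other'")
  ord <- panel_order(panel$chrom, panel$pos)
  if (!identical(ord, seq_len(nrow(panel))))
    stop("snp_panel must be sorted by (chrom, pos)")
  # positions strictly increasing per chromosome implies no duplicated pos
  if (anyDuplicated(paste(panel$chrom, panel$pos)))
    stop("duplicated (chrom, pos) in snp_panel")
  invisible(panel)
}

#' Generate a panel of population SNP sites
#'
#' Sites are scattered over autosomes 1-22 with minor allele frequencies
#' drawn from `maf_law` and a fraction of sites tagged as lying in 3' UTRs
#' (the regions retained by 3'-tag-protocol panel filtering).
#'
#' @param n_snps Number of sites (>= 0).
#' @param maf_law A [dist_uniform()] spec with support in (0, 0.5].
#' @param utr_fraction Probability that a site is tagged `three_prime_utr`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param n_chrom Number of chromosomes to scatter sites over.
#' @return A [snp_panel()] sorted by (chrom, pos).
#' @export
generate_snp_panel <- function(n_snps, maf_law = dist_uniform(0.05, 0.5),
                               utr_fraction = 0.25, seed = 1L,
                               n_chrom = 22L) {
  stopifnot(n_snps >= 0, utr_fraction >= 0, utr_fraction <= 1)
  check_dist_bounds(maf_law, 0, 0.5, "maf_law")
  if (n_snps == 0) {
    return(snp_panel(data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), maf = numeric(0), region_tag = character(0),
      origin = character(0), stringsAsFactors = FALSE)))
  }
  bases <- c("A", "C", "G", "T")
  with_rng(seed, {
    chrom <- as.character(sample.int(n_chrom, n_snps, replace = TRUE))
    # draw positions until unique within chromosome (collisions are rare at
    # ~1e8 bp per chromosome)
    pos <- sample.int(1e8L, n_snps, replace = TRUE)
    repeat {
      dup <- duplicated(paste(chrom, pos))
      if (!any(dup)) break
      pos[dup] <- sample.int(1e8L, sum(dup), replace = TRUE)
    }
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    df <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      maf = draw_dist(maf_law, n_snps),
      region_tag = ifelse(stats::runif(n_snps) < utr_fraction,
                          "three_prime_utr", "other"),
      origin = "germline", stringsAsFactors = FALSE)
    df <- df[panel_order(df$chrom, df$pos), , drop = FALSE]
    snp_panel(df)
  })
}

#' Filter a SNP panel by genomic region tag
#'
#' Mirrors the reference-building step that retains only 3' UTR SNPs for
#' 3'-tag sequencing protocols. The returned panel carries a `site_index`
#' attribute (indices into the input) so genotype matrices can be subset by
#' the same column mask via [subset_genotypes()].
#'
#' @param panel A [snp_panel()].
#' @param allowed_tags Character vector of region tags to retain.
#' @return The filtered panel, input order preserved.
#' @export
filter_panel_by_region <- function(panel, allowed_tags) {
  validate_snp_panel(panel)
  keep <- which(panel$region_tag %in% allowed_tags)
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_panel", "data.frame")
  attr(out, "site_index") <- keep
  out
}

#' Intersect two SNP panels
#'
#' Keeps records of `a` present in `b`, matched on (chrom, pos, ref, alt);
#' the result carries `a`'s MAFs and tags in `a`'s order. Sites sharing
#' (chrom, pos) but with conflicting alleles are excluded with a message.
#'
#' @param a,b [snp_panel()] objects.
#' @return Subset of `a`, with a `site_index` attribute into `a`.
#' @export
intersect_panels <- function(a, b) {
  validate_snp_panel(a); validate_snp_panel(b)
  key_a <- panel_key(a); key_b <- panel_key(b)
  pos_a <- paste(a$chrom, a$pos); pos_b <- paste(b$chrom, b$pos)
  keep <- which(key_a %in% key_b)
  conflict <- which(pos_a %in% pos_b & !(key_a %in% key_b))
  if (length(conflict)) {
    message(length(conflict),
            " shared position(s) with conflicting alleles excluded from",
            " panel intersection")
  }
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_panel", "data.frame")
  attr(out, "site_index") <- keep
  out
}

#' Randomly subsample a panel to emulate SNP-array content
#'
#' Stand-in for a commercial genotyping array's site list: a random subset
#' of the population panel, intersected downstream with a genotype
#' reference via [intersect_panels()].
#'
#' @param panel A [snp_panel()].
#' @param fraction Fraction of sites retained.
#' @param seed Integer seed.
#' @return A [snp_panel()] subset (sorted order preserved).
#' @export
sample_array_panel <- function(panel, fraction = 0.5, seed = 1L) {
  validate_snp_panel(panel)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(panel)
  keep <- with_rng(seed, sort(sample.int(n, round_half_away(fraction * n))))
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_panel", "data.frame")
  attr(out, "site_index") <- keep
  out
}
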