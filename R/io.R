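# --- MatrixMarket coordinate integer IO (cellSNP-style dialect) ---------

mm_header <- "%%MatrixMarket matrix coordinate integer general"

write_mm <- function(M, path) {
  Ts <- methods::as(M, "TsparseMatrix")
  ord <- order(Ts@j, Ts@i)
  lines <- c(mm_header,
             sprintf("%d %d %d", nrow(M), ncol(M), length(Ts@x)),
             sprintf("%d %d %d", Ts@i[ord] + 1L, Ts@j[ord] + 1L,
                     as.integer(Ts@x[ord])))
  writeLines(lines, path)
  invisible(path)
}

read_mm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "%%MatrixMarket"))
    stop(path, ":1: not a MatrixMarket file")
  if (!grepl("coordinate", lines[1]) || !grepl("general", lines[1]))
    stop(path, ":1: expected 'coordinate ... general' format, got: ",
         lines[1])
  body <- which(!startsWith(lines, "%") & nzchar(trimws(lines)))
  if (length(body) == 0) stop(path, ": no size line found")
  dims_line <- body[1]
  dims <- suppressWarnings(as.numeric(strsplit(trimws(lines[dims_line]),
                                               "\\s+")[[1]]))
  if (length(dims) != 3 || anyNA(dims))
    stop(path, ":", dims_line, ": malformed size line: ", lines[dims_line])
  nr <- dims[1]; nc <- dims[2]; nnz <- dims[3]
  entry_lines <- body[-1]
  if (length(entry_lines) != nnz)
    stop(path, ": expected ", nnz, " entries, found ", length(entry_lines))
  if (nnz == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(nr, nc)))
  parts <- strsplit(trimws(lines[entry_lines]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 3)
  if (length(bad))
    stop(path, ":", entry_lines[bad[1]], ": malformed entry: ",
         lines[entry_lines[bad[1]]])
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- entry_lines[which(rowSums(is.na(m)) > 0)[1]]
    stop(path, ":", bad, ": non-numeric entry: ", lines[bad])
  }
  out_of_range <- which(m[, 1] < 1 | m[, 1] > nr | m[, 2] < 1 | m[, 2] > nc)
  if (length(out_of_range))
    stop(path, ":", entry_lines[out_of_range[1]],
         ": index out of range: ", lines[entry_lines[out_of_range[1]]])
  Matrix::sparseMatrix(i = m[, 1], j = m[, 2], x = m[, 3],
                       dims = c(nr, nc))
}

# --- VCF export/import --------------------------------------------------

gt_string <- c("0/0", "0/1", "1/1")

#' Write a SNP panel (optionally with donor genotypes) as VCF
#'
#' VCFv4.2, chromosomes without a "chr" prefix, 1-based positions. MAF,
#' region tag and origin are carried in INFO; genotypes, when supplied,
#' as per-donor GT columns ("0/0", "0/1", "1/1", "./.").
#'
#' @param panel A [snp_panel()].
#' @param path Output file.
#' @param genotypes Optional [donor_genotypes()] aligned to the panel.
#' @return The path, invisibly.
#' @export
write_sites_vcf <- function(panel, path, genotypes = NULL) {
  validate_snp_panel(panel)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population minor allele frequency\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Region tag\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"germline or somatic\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(genotypes)) {
    validate_donor_genotypes(genotypes)
    stopifnot(ncol(genotypes$G) == nrow(panel))
    header <- c(header,
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    cols <- c(cols, "FORMAT", genotypes$donor_ids)
  }
  info <- sprintf("MAF=%s;REGION=%s;ORIGIN=%s",
                  ifelse(is.na(panel$maf), ".",
                         formatC(panel$maf, digits = 8, format = "g")),
                  panel$region_tag, panel$origin)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  panel$chrom, panel$pos, panel$ref, panel$alt, info)
  if (!is.null(genotypes)) {
    gt <- apply(genotypes$G, 2L, function(g)
      paste(ifelse(is.na(g), "./.", gt_string[g + 1L]), collapse = "\t"))
    if (nrow(panel) == 0) gt <- character(0)
    body <- paste(body, "GT", gt, sep = "\t")
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a sites VCF back into a SNP panel (and genotypes if present)
#'
#' @param path VCF file written by [write_sites_vcf()] (or compatible).
#' @return List with `panel` ([snp_panel()]) and `genotypes` (a
#'   [donor_genotypes()], or NULL for a sites-only VCF).
#' @export
read_sites_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  get_info <- function(key) {
    if (n == 0) return(character(0))
    m <- regmatches(fix$INFO,
                    regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
    sub(paste0("^;?", key, "="), "", m)
  }
  maf <- suppressWarnings(as.numeric(get_info("MAF")))
  panel <- snp_panel(data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, maf = maf,
    region_tag = if (n) get_info("REGION") else character(0),
    origin = if (n) get_info("ORIGIN") else character(0),
    stringsAsFactors = FALSE))
  genotypes <- NULL
  if (ncol(vcf@gt) > 1) {
    gt <- vcfR::extract.gt(vcf)
    G <- t(apply(gt, 2L, function(col)
      match(col, gt_string) - 1L))
    if (n == 1) G <- matrix(G, ncol = 1L,
                            dimnames = list(colnames(vcf@gt)[-1], NULL))
    genotypes <- donor_genotypes(G, donor_ids = colnames(vcf@gt)[-1])
  }
  list(panel = panel, genotypes = genotypes)
}

# --- Allele-count directory layout --------------------------------------

#' Write allele counts as a cellSNP-style directory
#'
#' Writes `AD.mtx` and `DP.mtx` (MatrixMarket coordinate integer, 1-based,
#' barcodes in rows), `barcodes.tsv` (one barcode per line, no header) and
#' `sites.vcf` for the panel.
#'
#' @param counts An [allele_counts()].
#' @param panel The matching [snp_panel()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_allele_counts <- function(counts, panel, dir) {
  validate_allele_counts(counts); validate_snp_panel(panel)
  stopifnot(ncol(counts$AD) == nrow(panel))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mm(counts$AD, file.path(dir, "AD.mtx"))
  write_mm(counts$DP, file.path(dir, "DP.mtx"))
  writeLines(counts$barcodes, file.path(dir, "barcodes.tsv"))
  write_sites_vcf(panel, file.path(dir, "sites.vcf"))
  invisible(dir)
}

#' Read an allele-count directory written by [write_allele_counts()]
#'
#' Exact inverse: values, ordering and barcodes roundtrip identically.
#'
#' @param dir Directory path.
#' @return List with `counts` ([allele_counts()]) and `panel`.
#' @export
read_allele_counts <- function(dir) {
  AD <- read_mm(file.path(dir, "AD.mtx"))
  DP <- read_mm(file.path(dir, "DP.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (length(barcodes) == 0) barcodes <- character(0)
  panel <- read_sites_vcf(file.path(dir, "sites.vcf"))$panel
  list(counts = allele_counts(barcodes, AD, DP), panel = panel)
}

# --- TSV serializers ----------------------------------------------------

#' Write/read ground-truth labels as TSV
#'
#' Columns: barcode, label_type, donor_a, donor_b, somatic_sites.
#' @param truth A [cell_truth()].
#' @param path File path.
#' @return The path (write) or a [cell_truth()] (read).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "integer", "integer", "character"),
                          na.strings = "", stringsAsFactors = FALSE)
  df$somatic_sites[is.na(df$somatic_sites)] <- ""
  cell_truth(df$barcode, df$label_type, df$donor_a, df$donor_b,
             df$somatic_sites)
}

#' Write a demultiplexing result as TSV
#'
#' Columns: barcode, call, donor_or_pair, max_posterior, posterior
#' (semicolon-delimited full vector).
#'
#' @param result A `demux_result`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_assignments <- function(result, path) {
  post <- attr(result, "posterior")
  donor_or_pair <- ifelse(
    result$call == "singlet", paste0("donor", result$donor_a),
    ifelse(result$call == "doublet",
           paste0("donor", result$donor_a, "+donor", result$donor_b), ""))
  df <- data.frame(barcode = result$barcode, call = result$call,
                   donor_or_pair = donor_or_pair,
                   max_posterior = formatC(result$max_posterior,
                                           digits = 8, format = "g"),
                   posterior = apply(post, 1L, function(p)
                     paste(formatC(p, digits = 6, format = "g"),
                           collapse = ";")),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
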