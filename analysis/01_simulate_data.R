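#!/usr/bin/env Rscript

# Build the benchmark's synthetic pooled dataset under the study
# conditions (3 cancer donors, germline SNP panel plus somatic SNVs and
# CNV allele skew) and write the clean and perturbed pools to
# results/data/ in the cellSNP-style layout.

library(demuxbench)

seed <- 20260901L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- generate_snp_panel(1000, utr_fraction = 0.25, seed = seed)
geno <- generate_donor_genotypes(panel, K = 3, seed = derive_seed(seed, "geno"))
ext <- apply_somatic_snvs(geno, panel, tmb_per_mb = 20, covered_mb = 10,
                          seed = derive_seed(seed, "somatic"))
geno <- apply_cnv_allele_skew(ext$genotypes, fraction_of_sites = 0.2,
                              seed = derive_seed(seed, "cnv"))
panel <- ext$panel
message("panel: ", nrow(panel), " sites, of which ",
        sum(panel$origin == "somatic"), " donor-private somatic")

sim <- simulate_cell_counts(geno, panel, cell_sim_config(
  cells_per_donor = c(120, 120, 120), mean_site_depth = 1.0,
  seed = derive_seed(seed, "cells")))
message("clean pool: ", length(sim$counts$barcodes), " cells, mean depth/cell ",
        round(mean(Matrix::rowSums(sim$counts$DP)), 1), " reads over SNPs")
write_allele_counts(sim$counts, panel, file.path(out, "clean"))
write_truth(sim$truth, file.path(out, "clean_truth.tsv"))
write_sites_vcf(panel, file.path(out, "genotypes.vcf"), geno)

# 30% doublets, then 20% ambient debris on top
db <- simulate_doublets(sim$counts, sim$truth, 0.30,
                        seed = derive_seed(seed, "doublets"))
message("doublets: ", nrow(db$plan), " merges -> ",
        length(db$counts$barcodes), " final barcodes (",
        round(100 * nrow(db$plan) / length(db$counts$barcodes), 1),
        "% doublets)")
write_allele_counts(db$counts, panel, file.path(out, "doublets30"))
write_truth(db$truth, file.path(out, "doublets30_truth.tsv"))

de <- simulate_debris(db$counts, db$truth, 0.20,
                      seed = derive_seed(seed, "debris"))
message("debris: ", nrow(de$plan), " barcodes lysed; reads conserved: ",
        sum(de$counts$DP) == sum(db$counts$DP))
write_allele_counts(de$counts, panel, file.path(out, "doublets30_debris20"))
write_truth(de$truth, file.path(out, "doublets30_debris20_truth.tsv"))
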