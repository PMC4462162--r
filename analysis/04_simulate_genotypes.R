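#!/usr/bin/env Rscript

# Generates the desk-scale genotype panel for the SNP-heritability track:
# 1000 unrelated individuals x 2000 HWE SNPs with 500 causal variants and a
# planted SNP heritability of 0.4.  Writes PLINK bed/bim/fam plus the
# phenotype and ground truth.

library(famvar)

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
dir.create("results", showWarnings = FALSE)

sim <- simulate_genotype_phenotype(n_ind = 1000, n_snp = 2000,
                                   h2_snp = 0.4, seed = seed)
write_plink_bed(sim$genotypes, "results/panel")
write.table(data.frame(id = sim$genotypes$ids, trait = sim$phenotype),
            "results/panel_phenotype.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(h2_snp_target = sim$truth$h2_snp_target,
                          h2_snp_realized = sim$truth$h2_snp_realized,
                          n_causal = length(sim$truth$causal), seed = seed),
                     "results/panel_truth.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("Panel: %d individuals x %d SNPs; realised h2 = %.3f (target 0.4)\n",
            1000, 2000, sim$truth$h2_snp_realized))
cat("wrote results/panel.{bed,bim,fam} and phenotype\n")
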