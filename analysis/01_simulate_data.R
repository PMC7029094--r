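#!/usr/bin/env Rscript
# Generate the synthetic inputs every downstream analysis consumes: a
# spaced SNP panel, a larval cohort with a known pedigree, weakly
# structured populations, and length-at-age data. Writes a VCF and a
# metadata TSV under results/.

suppressPackageStartupMessages(library(lampreykin))
set.seed(20200115)
dir.create("results", showWarnings = FALSE)

# SNP panel: 1,000 loci, U-shaped frequency spectrum, >= 2 Mb spacing
panel <- draw_allele_frequencies(1000, loci_per_scaffold = 20L)
cat(sprintf("panel: %d loci on %d scaffolds, mean MAF %.3f\n",
            nrow(panel), length(unique(panel$scaffold)),
            mean(panel_maf(panel))))

# one cohort: 50 adults, 100 sampled offspring, sequencing-like noise
sim <- simulate_cohort(sim_config(50, n_loci = 500),
                       error_rate = 0.01, missing_rate = 0.05)
write_vcf(sim$gm, "results/cohort.vcf")
utils::write.csv(sim$pedigree, "results/cohort_pedigree.csv",
                 row.names = FALSE)
cat(sprintf("cohort: %d offspring of %d adults -> results/cohort.vcf\n",
            nrow(sim$gm$geno),
            length(unique(c(sim$pedigree$mother_id,
                            sim$pedigree$father_id)))))

# weak structure: 5 populations at F_ST 0.01 (the panel's survey regime)
pops <- structured_populations(panel, 5, 0.01, 25)
pops <- corrupt_genotypes(pops, error_rate = 0.005, missing_rate = 0.03)
write_vcf(pops, "results/populations.vcf")

# lengths: 4-component Gaussian mixture of ages 0 / 1 / 2 / 3+
lengths <- simulate_lengths(age_mixture(), 250)
meta <- data.frame(
  sample_id = sprintf("larva_%03d", seq_len(nrow(lengths))),
  population = "sim_stream",
  location = sample(paste0("site_", 1:6), nrow(lengths), replace = TRUE),
  length_mm = round(lengths$length_mm, 1),
  cohort = lengths$age
)
write_metadata(meta, "results/metadata.tsv")
cat(sprintf("metadata: %d larvae across %d sites -> results/metadata.tsv\n",
            nrow(meta), length(unique(meta$location))))
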