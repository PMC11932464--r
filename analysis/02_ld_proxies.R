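#!/usr/bin/env Rscript
# Step 2 -- proxy-SNP selection: compute pairwise LD on the simulated
# panel and select all proxies of a lead SNP inside the strong-LD block at
# r2 > 0.8, the same criterion used to expand a GWAS lead into its
# haplotype block.

suppressPackageStartupMessages(library(regvarscreen))
panel <- read_haplotypes_tsv("results/haplotype_panel.tsv")

# the middle block spans sites 6..19; take its first site as the lead
lead <- "snp_006"
ps <- select_proxies(panel, lead, r2_threshold = 0.8, window_bp = 500000)
write_proxies_tsv(ps, "results/proxies.tsv")
cat("lead", lead, "has", nrow(ps$proxies), "proxies at r2 >=",
    ps$threshold, "-> results/proxies.tsv\n")
cat("(the 13 other block members are expected; between-block sites",
    "were shuffled apart)\n")

# allele-frequency arithmetic on the printed EUR genotype frequencies
f_c <- allele_freq_from_genotype_freqs(0.155, 0.485, 0.360)
cat(sprintf("EUR C-allele frequency from genotype frequencies: %.4f (%.3f at 3 decimals)\n",
            f_c, round_half_up(f_c, 3)))
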