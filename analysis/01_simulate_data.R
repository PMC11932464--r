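#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic study inputs with known ground truth:
# a phased haplotype panel with one strong-LD block (emulating the
# associated enhancer haplotype block), an enhancer-like sequence with
# three planted CEBPB-like motifs spaced exactly 1,427 bp apart, an
# allelic sequence pair whose SNP destroys the motif anchor, and qPCR Ct
# tables with programmed fold changes.

suppressPackageStartupMessages(library(regvarscreen))
dir.create("results", showWarnings = FALSE)
seed <- 1L

## haplotype panel: one 14-site block in near-perfect LD plus two outside
## blocks, 300 phased haplotypes
panel <- simulate_haplotype_panel(300, c(5, 14, 5),
                                  between_block_shuffle = 0.9,
                                  maf_range = c(0.3, 0.45), seed = seed)
write_haplotypes_tsv(panel, "results/haplotype_panel.tsv")
cat("simulated", nrow(panel$alleles), "haplotypes x",
    ncol(panel$alleles), "sites -> results/haplotype_panel.tsv\n")

## enhancer sequence with three planted motifs spaced 1,427 bp apart
motif <- cebpb_like_pfm()
plant_positions <- c(401, 1828, 3255)  # anchors differ by exactly 1427
spec <- motif_plant_spec(motif, plant_positions, rep("+", 3),
                         length = 4000, seed = seed)
enhancer <- plant_motifs(spec)
write_fasta(c(enhancer_synthetic = enhancer), "results/enhancer.fa")
write_bed(planted_truth_intervals(spec, chrom = "enhancer_synthetic"),
          "results/planted_motifs.bed")
cat("planted", length(plant_positions), "consensus motifs in a 4 kb",
    "sequence -> results/enhancer.fa + planted_motifs.bed\n")

## allelic pair: SNP at the motif anchor column (offset 4), reference
## carries the consensus C
pair <- make_allelic_pair(motif, flank = 21, snp_offset_in_motif = 4,
                          ref_is_consensus = TRUE, seed = seed)
write_fasta(c(rs_synth_ref = pair$seq_ref, rs_synth_alt = pair$seq_alt),
            "results/allele_pair.fa")
cat("allelic pair of length", nchar(pair$seq_ref), "differing at index",
    pair$snp_index, "-> results/allele_pair.fa\n")

## Ct tables: programmed 25-fold induction, with and without noise
for (sd in c(0, 0.3)) {
  tb <- simulate_ct_table(ct_table_spec(25, noise_sd = sd,
                                        n_replicates = 3, seed = seed),
                          conditions = c("crispra", "scramble"),
                          genes = c("SOST", "GAPDH"))
  f <- sprintf("results/ct_table_sd%s.tsv", sd)
  write.table(tb, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("Ct table (noise sd", sd, ") ->", f, "\n")
}
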