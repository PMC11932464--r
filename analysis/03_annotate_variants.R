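#!/usr/bin/env Rscript
# Step 3 -- chromatin-element annotation: intersect candidate variants
# with element tracks (here the two published CEBPB ChIP-seq peak spans
# plus synthetic DHS/H3K27ac intervals) and classify each variant's
# regulatory context.

suppressPackageStartupMessages(library(regvarscreen))

peaks <- read_bed(system.file("extdata", "cebpb_chipseq_peaks.bed",
                              package = "regvarscreen"))
# synthetic enhancer-mark intervals covering the region around the peaks
marks <- genomic_intervals(
  chrom = rep("chr17", 3),
  start = c(41810200L, 41810250L, 41813300L),
  end = c(41810700L, 41812100L, 41813450L),
  label = c("DHS", "H3K27ac", "DHS"))
tracks <- rbind(peaks, marks)
class(tracks) <- c("genomic_intervals", "data.frame")

variants <- data.frame(
  chrom = "chr17",
  pos = c(41810515L, 41811942L, 41813369L),
  id = c("peak1_C", "peak2_C", "rs9783823_like"))
ann <- intersect_variants(variants, tracks)
write_annotations_tsv(ann, "results/variant_annotations.tsv")
for (i in seq_len(nrow(ann))) {
  cat(sprintf("%-14s overlaps [%s] -> %s\n", ann$id[i],
              paste(ann$overlapping[[i]], collapse = ", "),
              ann$regulatory_class[i]))
}
cat("note: the rs9783823-like site sits outside both ChIP-seq peaks,\n")
cat("matching the absence of a CEBPB peak there in T/T-homozygous cells\n")
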