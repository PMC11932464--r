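# regvarscreen

An R package for in-silico screening of candidate *functional* variants
inside an associated haplotype block: which of the many statistically
interchangeable SNPs on an enhancer actually changes transcription-factor
(TF) binding?

The package implements the desk half of a regulatory-genetics study of the
*SOST* (sclerostin) locus, where a haplotype block associated with bone
mineral density and periodontitis contains an enhancer with three equally
spaced C/EBPβ (CEBPB) binding motifs, one of which is created/destroyed by
the C/T alleles of a single SNP. Every step is reusable on other loci:

1. **LD / proxy selection** (`pairwise_ld`, `select_proxies`) — expand a
   GWAS lead into its haplotype block from phased haplotypes:
   r² = D²/(p_A(1−p_A)p_B(1−p_B)) with D = p_AB − p_A p_B, proxies at
   r² > 0.8.
2. **Chromatin annotation** (`intersect_variants`, `classify_regulatory`)
   — intersect variants with DHS / H3K27ac / H3K4me1 / TF-ChIP / ChromHMM
   tracks (BED, 0-based half-open) and classify their regulatory context.
3. **Motif models** (`build_pwm`, `scan_pwm`) — JASPAR/MEME motif parsing,
   log₂-odds scanning on both strands, relative scores
   (s − s_min)/(s_max − s_min) that are 1.0 exactly on the consensus.
4. **Biophysical affinity** (`trap_affinity`, `calibrate_null`,
   `affinity_pvalue`) — TRAP-type expected occupancy
   Σᵢ R₀e^(−Eᵢ)/(1 + R₀e^(−Eᵢ)) with mismatch energies
   Eᵢ = (1/λ)Σⱼ ln[(n(b_max,j)+pc)/(n(b_ij,j)+pc)], λ = 0.7,
   ln R₀ = 0.584·W − 5.66, and empirical p-values against a seeded
   background null.
5. **Allele-differential screen** (`score_allele_pair`, `run_screen`) —
   per-allele affinity p-values, Δlog₁₀p (positive = reference binds more
   strongly), Bonferroni-combined two-allele p, Benjamini–Hochberg
   q-values, motif-congruence checks, deterministic ranking.
6. **Motif spacing** (`spacing_analysis`) — maximal arithmetic
   progressions (length ≥ 3) among motif anchor coordinates; this is how
   the exact 1,427 bp double spacing of the three CEBPB motifs is found.
7. **Assay arithmetic** (`ddct_fold_change`, `reporter_normalize`) —
   2^−ΔΔCt qPCR quantification with replicate t-tests and dual-luciferase
   firefly/renilla normalisation.
8. **Synthetic data** (`simulate_haplotype_panel`, `plant_motifs`,
   `make_allelic_pair`, `simulate_ct_table`) — seed-deterministic
   generators with known ground truth, so the whole pipeline is testable
   offline.

## Worked example

The `analysis/` directory holds the numbered drivers
(`01_simulate_data.R` … `05_assays.R`); each writes its tables under
`results/`. The core of the screen in a few lines:

```r
library(regvarscreen)

motif <- cebpb_like_pfm()            # synthetic CEBPB-like PFM, ~10.6 bits
pair  <- make_allelic_pair(motif, flank = 21, snp_offset_in_motif = 4,
                           ref_is_consensus = TRUE, seed = 1)
null  <- calibrate_null(motif, uniform_background(), nchar(pair$seq_ref),
                        n_null = 2000, seed = 1)
score_allele_pair(motif, pair$seq_ref, pair$seq_alt, pair$snp_index, null,
                  snp_id = "rs_synth")
```

prints (one row):

```
        tf_id  snp_id        p_ref     p_alt  p_combined    dlogp best_rel_score congruent preferred_allele
1 CEBPB_synth rs_synth 0.0004997501 0.1869065 0.0009995002 2.572872              1      TRUE              ref
```

The reference allele (consensus C at the anchor column) saturates the
empirical null (p = 1/2001), the alternative allele behaves like
background (p ≈ 0.19), so the SNP shows a ~2.6 decade allele difference,
a perfect relative PWM score, and the motif prefers the reference allele
— the same qualitative signature reported for rs9783823 (strong binding
on C, none on T). And the spacing of the three published motif anchors:

```r
spacing_analysis(c(41810515, 41811942, 41813369))$progressions
#   start_anchor common_difference length
# 1     41810515              1427      3
```

one arithmetic progression: peak1 → peak2 → rs9783823 site, each step
exactly 1,427 bp.

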