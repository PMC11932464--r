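---
title: "Screening haplotype blocks for allele-specific TF binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening haplotype blocks for allele-specific TF binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regvarscreen)
```

## The problem

A GWAS association names a haplotype block, not a mechanism. Within a
block, tens of SNPs are statistically interchangeable (r² near 1), so
association evidence alone cannot say which variant is functional. For
cis-regulatory variants a standard desk strategy is: expand the lead SNP
into its proxy set, keep the proxies that fall on biochemically active
enhancer chromatin, and ask — for every transcription factor motif —
whether the two alleles of each candidate are predicted to bind the
factor differently. regvarscreen implements that strategy end to end,
plus the quantification arithmetic for the perturbation assays (CRISPRa
qPCR, dual-luciferase reporters) that typically follow, and a
synthetic-data module that makes the whole pipeline testable with known
ground truth.

## Models and procedures

### Linkage disequilibrium

LD is computed exactly from phased haplotypes: with `1`-allele
frequencies $p_A$, $p_B$ and joint frequency $p_{AB}$,

$$D = p_{AB} - p_A p_B, \qquad
  r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad
  D' = |D| / D_\max.$$

There is no EM estimation from unphased genotypes: reference panels are
phased, and the exact computation keeps the module free of convergence
questions. Monomorphic sites raise an error rather than silently
returning 0 — an undefined r² almost always signals an upstream data
problem. The proxy window defaults to 500 kb, generous for a single
enhancer locus; the r² threshold defaults to the conventional 0.8.

### Chromatin annotation

Intervals are 0-based half-open internally (BED convention); a variant
at 1-based position $p$ overlaps $[s, e)$ iff $s \le p-1 < e$. Printed
browser-style spans ("chr17:41,810,335-41,810,590") are 1-based fully
closed and must be converted with `closed1_to_halfopen0()`. The
overlap computation itself is delegated to GenomicRanges.

The strong/weak enhancer classification is a formalisation this package
had to choose, because descriptive usage ("the SNP maps to DHS and
H3K27ac") does not define a rule. The default — strong when a ChromHMM
strong-enhancer state overlaps or when DHS co-occurs with H3K27ac or
H3K4me1; weak when a weak-enhancer state or exactly one mark overlaps;
promoter-proximal only as a fallback — is config-overridable
(`default_classification_rule()`), and tests verify it against an
independent truth table rather than against biology.

### Motif scoring and biophysical affinity

PWMs use background-distributed pseudocounts
($p(b,j) = (n(b,j) + 0.8\,\pi_b)/(N_j + 0.8)$, the JASPAR-ecosystem
convention) and log₂ odds. The *relative score*
$(s - s_\min)/(s_\max - s_\min)$ is 1 exactly on the consensus word,
which is how a printed "PWM = 0.98" style score is interpreted here.

Binding affinity uses the biophysical occupancy model: each window $i$
gets a mismatch energy

$$E_i = \frac{1}{\lambda} \sum_j
  \ln\frac{n(b_{\max,j}, j) + pc}{n(b_{ij}, j) + pc}$$

(natural log; $pc = 0.8$) and the sequence's expected occupancy is
$\sum_i R_0 e^{-E_i} / (1 + R_0 e^{-E_i})$ over both strands, with
$\lambda = 0.7$ and $\ln R_0 = 0.584\,W - 5.66$ by default. These
defaults are the published calibration of the occupancy model; all are
exposed in `trap_params()` because none is sacred.

P-values are *empirical*: `calibrate_null()` draws `n_null` background
sequences of the same length, and
$p = (1 + \#\{\text{null} \ge \text{occ}\})/(n_{\text{null}} + 1)$.
The +1 makes p-values valid (super-uniform) and bounded away from 0 at
$1/(n_{\text{null}}+1)$ — so the resolution of small p-values is set by
`n_null`, and published p-values from tools with analytic extreme-value
tails (e.g. $7.7\times10^{-7}$) can only be matched in ordering and
order of magnitude, never digit-for-digit. Tests therefore assert
ordering and thresholds, not equality.

The 'human promoters' background used by the original web tool is not
published; the shipped default is a uniform order-0 model, with a
GC-rich, CpG-depleted order-1 preset (`promoter_background()`) for
sensitivity analyses.

### The allele-differential screen

For each motif × SNP, both allele sequences are scored against the same
null; the effect size is $\Delta\log p = \log_{10} p_{alt} -
\log_{10} p_{ref}$ (positive = reference binds more strongly). The
combined per-test p-value is Bonferroni over the two alleles,
$\min(1, 2\min(p_{ref}, p_{alt}))$ — the combination rule of the
original multi-sequence tool is unpublished, so the conservative,
documented choice was made. BH correction runs across all motif × SNP
tests (via `stats::p.adjust`; the test suite checks it against a
hand-written step-up). Ranking ties break by |Δlog p| descending, then
tf_id, then snp_id, making reports permutation-invariant. The fixed
exploratory cut $5\times10^{-6}$ from the original screen is available
as an optional raw-p pre-filter, not as the default significance rule.

Congruence formalises the manual "does the SNP actually sit in the
motif" check: the SNP must fall inside the best-scoring hit window and
the PWM column there must prefer one allele over the other by a
probability ratio ≥ 2 (configurable). Minus-strand hits are assessed on
complemented alleles.

`spacing_analysis()` enumerates maximal arithmetic progressions
(length ≥ 3, exact by default, `tolerance_bp` for slack) among motif
anchor coordinates — the anchor being the motif's maximum-information
column, e.g. the invariant C of a C/EBP site. On the three published
anchor coordinates it returns the single progression with common
difference 1,427 bp.

### Assay arithmetic

`ddct_fold_change()` implements classical 2^−ΔΔCt with PCR efficiency
fixed at 2 (efficiency-corrected variants are out of scope);
replicate-paired ΔCt when replicate indices align across genes, with a
condition-mean fallback (and a message) otherwise, since source tables
do not always state the pairing. The t-test on per-replicate ΔCt is
Welch by default — "a t-test" without qualification is safest as the
unequal-variance form — switchable via `var_equal`. Zero-variance
(noiseless) inputs return NA rather than an error.
`reporter_normalize()` is the standard per-well firefly/renilla ratio,
averaged per construct and scaled to the control construct.

## The synthetic-data module

The generators define the study conditions for every test:

* **Haplotype panels**: founder columns copied within blocks (r² = 1 by
  construction) and per-block label shuffling between blocks. This is
  deliberately not a coalescent simulation — the screen consumes only
  r², and copying/shuffling gives exact control over it. Default MAF
  range (0.05, 0.5); the drivers use 300 haplotypes, matching the scale
  of a pooled two-population reference panel.
* **Motif plants**: consensus words (argmax per column, ties A<C<G<T)
  written verbatim into background sequence; plants may not overlap.
* **Allelic pairs**: 21 bp flanks on each side of the motif — the probe
  geometry used for EMSA oligonucleotides — with the SNP at a chosen
  motif column, consensus base vs minimum-probability base.
* **Ct tables**: treated-target mean shifted by −log₂(fold change),
  reference gene flat, i.i.d. Gaussian per-well noise (the standard
  desk-scale qPCR error model), defaults 3 replicates and SD 0.3
  cycles.

What passing tests on these fixtures show — and what they do not: the
generators produce clean blocks, exact consensus plants, uppercase
ACGT-only sequences and Gaussian noise. Real panels have partial LD and
population structure, real enhancers have degenerate motif instances
and repeats, and real qPCR has plate effects and efficiency drift. The
tests therefore validate the *computations*, not the biology.

The bundled `cebpb_like_pfm()` is a synthetic stand-in (the curated
database matrix is not redistributed here): consensus ATTGCACAAT around
the canonical TTGCACAA half-site pair, ~10.6 bits, with a nearly
invariant central C as anchor. The consensus is intentionally
non-palindromic: with a perfect palindrome, an anchor-destroying SNP is
rescued by the reverse-strand match and the allele-differential signal
collapses — a genuinely instructive failure mode of allele-level motif
scoring.

## Numerical choices and calibrated bounds

* Log base 2 for log-odds, natural log inside energies — each follows
  its source convention; mixing them silently is a classic bug, so both
  are stated in the function docs.
* Consensus and argmin ties break by fixed base order A<C<G<T.
* Relative-score thresholds compare with a 1e-9 slack so the consensus
  window is never lost to floating-point summation order.
* `round_half_up()` exists because published frequencies round 0.3975
  to 0.398 (half-up), while R's `round()` is half-to-even; it guards
  against binary representation error before the half-up step.
* Empirically calibrated test bounds (fixed before freezing the tests,
  under the default conditions above): allele-destroying SNPs in the
  ~10.6-bit motif give Δlog p in [1.79, 2.59] across 20 seeds at
  n_null = 2000, frozen bound ≥ 1.5; background-position SNPs give
  |Δlog p| up to 0.93 across 50 seeds, frozen bound < 1.2. The two
  regimes stay separated by the ranking statistic.
* Problem sizes in tests and the acceptance script (n_null = 1000–2000,
  20 recovery seeds, 50–100 null-screen seeds, 200 ddCt seeds, 52 bp
  allele sequences) were chosen as the smallest sizes at which the
  Monte-Carlo bounds above are stable.

## Known limitations

* Empirical p-values cannot resolve below 1/(n_null+1); genome-scale
  screens would need analytic tail approximations.
* The two-allele Bonferroni combination is conservative; a method that
  models the occupancy difference directly would gain power.
* Order-1 backgrounds are the highest supported; CpG-island-like
  contexts may need higher order.
* `spacing_analysis()` is O(n³) in anchors with greedy extension under
  tolerance — exact for the exact-spacing case, heuristic for large
  tolerances with dense anchor sets.
* Multi-allelic sites, unphased genotypes and IUPAC ambiguity codes are
  out of scope by design.

## A minimal run

```{r example}
motif <- cebpb_like_pfm()
pair <- make_allelic_pair(motif, flank = 21, snp_offset_in_motif = 4,
                          ref_is_consensus = TRUE, seed = 1)
null <- calibrate_null(motif, uniform_background(), nchar(pair$seq_ref),
                       n_null = 500, seed = 1)
score_allele_pair(motif, pair$seq_ref, pair$seq_alt, pair$snp_index,
                  null, snp_id = "rs_synth")

spacing_analysis(c(41810515, 41811942, 41813369))$progressions
```
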