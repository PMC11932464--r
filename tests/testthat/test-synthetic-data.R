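test_that("every generator is seed-deterministic", {
  p1 <- simulate_haplotype_panel(100, c(5, 3), 0.3, c(0.1, 0.4), seed = 7)
  p2 <- simulate_haplotype_panel(100, c(5, 3), 0.3, c(0.1, 0.4), seed = 7)
  expect_identical(p1$alleles, p2$alleles)
  expect_identical(p1$sites, p2$sites)

  m <- cebpb_like_pfm()
  sp <- motif_plant_spec(m, c(11, 40), c("+", "-"), length = 80, seed = 3)
  expect_identical(plant_motifs(sp), plant_motifs(sp))

  a1 <- make_allelic_pair(m, 21, 4, TRUE, seed = 5)
  a2 <- make_allelic_pair(m, 21, 4, TRUE, seed = 5)
  expect_identical(a1, a2)

  ct <- ct_table_spec(4, noise_sd = 0.5, n_replicates = 3, seed = 9)
  expect_identical(simulate_ct_table(ct), simulate_ct_table(ct))
})

test_that("haplotype panel honours its invariants and LD structure", {
  pan <- simulate_haplotype_panel(100, 5, 0, c(0.2, 0.2), seed = 1)
  expect_true(all(pan$alleles %in% 0:1))
  expect_true(all(diff(pan$sites$pos) > 0))
  # within-block columns are copies: all pairwise r2 = 1
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(pairwise_ld(pan, i, j)$r2, 1.0)
  }
  # allele frequencies near the programmed maf (binomial tolerance)
  freqs <- colMeans(pan$alleles)
  freqs <- pmin(freqs, 1 - freqs)
  expect_true(all(abs(freqs - 0.2) < 4 * sqrt(0.2 * 0.8 / 100)))

  expect_error(simulate_haplotype_panel(101, 5, 0, c(0.2, 0.2), seed = 1),
               "even")
  expect_error(simulate_haplotype_panel(100, 5, 0, c(0, 0.6), seed = 1),
               "maf_range")
})

test_that("full between-block shuffling makes blocks independent", {
  r2_means <- vapply(1:50, function(s) {
    pan <- simulate_haplotype_panel(2000, c(3, 3), between_block_shuffle = 1,
                                    maf_range = c(0.2, 0.4), seed = s)
    mean(vapply(1:3, function(i) {
      mean(vapply(4:6, function(j) pairwise_ld(pan, i, j)$r2, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean(r2_means), 0.05)
})

test_that("planted consensus sites are written verbatim and recoverable", {
  m <- cebpb_like_pfm()
  w <- ncol(m$counts)
  sp <- motif_plant_spec(m, 21, "+", length = 60, seed = 2)
  seq <- plant_motifs(sp)
  expect_equal(nchar(seq), 60)
  expect_equal(substr(seq, 21, 20 + w), consensus_word(m))
  hits <- scan_pwm(build_pwm(m), seq, rel_threshold = 0.99)
  hits <- hits[hits$strand == "+", ]
  expect_true(any(hits$start == 21 & abs(hits$rel_score - 1) < 1e-12))

  # anchors of three plants spaced 1427 apart form one exact progression
  anchors <- c(100, 1527, 2954) + build_pwm(m)$anchor_col - 1
  sp3 <- motif_plant_spec(m, c(100, 1527, 2954), length = 3100, seed = 4)
  seq3 <- plant_motifs(sp3)
  hits3 <- scan_pwm(build_pwm(m), seq3, rel_threshold = 0.999)
  got <- spacing_analysis(sort(hits3$anchor_pos[hits3$strand == "+"]))
  expect_equal(nrow(got$progressions), 1L)
  expect_equal(got$progressions$common_difference, 1427)
  expect_equal(got$progressions$length, 3L)

  expect_error(motif_plant_spec(m, c(10, 15), c("+", "+"), length = 60,
                                seed = 1), "overlap")
  expect_error(motif_plant_spec(m, 5, "+", length = 8, seed = 1), "wider")
})

test_that("plant-free background matches its base composition", {
  bg <- background_model(base_freqs = c(0.4, 0.1, 0.1, 0.4))
  m <- cebpb_like_pfm()
  sp <- motif_plant_spec(m, integer(), background = bg, length = 100000,
                         seed = 6)
  seq <- plant_motifs(sp)
  obs <- table(factor(strsplit(seq, "")[[1]], levels = BASES)) / 100000
  for (b in seq_along(BASES)) {
    p <- c(0.4, 0.1, 0.1, 0.4)[b]
    se <- sqrt(p * (1 - p) / 100000)
    expect_lt(abs(obs[[b]] - p), 3 * se)
  }
})

test_that("allelic pairs have the stated geometry and allele assignment", {
  m <- cebpb_like_pfm()  # width 10
  pr <- make_allelic_pair(m, flank = 21, snp_offset_in_motif = 4,
                          ref_is_consensus = TRUE, seed = 3)
  expect_equal(nchar(pr$seq_ref), 21 + 10 + 21)
  expect_equal(nchar(pr$seq_alt), 52)
  d <- which(strsplit(pr$seq_ref, "")[[1]] != strsplit(pr$seq_alt, "")[[1]])
  expect_equal(d, pr$snp_index)
  expect_equal(pr$snp_index, 21 + 4 + 1)

  # the consensus-carrying allele scores strictly higher
  w <- build_pwm(m)
  best <- function(s) max(scan_pwm(w, s, rel_threshold = 0)$rel_score)
  expect_gt(best(pr$seq_ref), best(pr$seq_alt))

  flat <- pfm("flat", matrix(c(5, 5, 5, 5, 9, 1, 1, 1), nrow = 4))
  expect_error(make_allelic_pair(flat, 5, 0, TRUE, seed = 1),
               "non-informative column")
})

test_that("allele-destroying SNPs give a large calibrated dlogp", {
  # bound frozen after a 20-seed calibration at n_null = 2000
  m <- cebpb_like_pfm()
  null <- calibrate_null(m, uniform_background(), 52, 2000, seed = 101)
  dl <- vapply(1:5, function(s) {
    pr <- make_allelic_pair(m, 21, 4, TRUE, seed = s)
    score_allele_pair(m, pr$seq_ref, pr$seq_alt, pr$snp_index, null,
                      snp_id = "eff")$dlogp
  }, numeric(1))
  expect_true(all(dl >= 1.5))
})

test_that("simulated Ct tables encode the programmed fold change", {
  sp <- ct_table_spec(4, baseline_ct_target = 25, baseline_ct_reference = 18,
                      noise_sd = 0, n_replicates = 3, seed = 1)
  tb <- simulate_ct_table(sp)
  treated_target <- tb$ct[tb$condition == "treated" & tb$gene == "target"]
  control_target <- tb$ct[tb$condition == "control" & tb$gene == "target"]
  expect_equal(unique(treated_target), 25 - log2(4))
  expect_equal(unique(control_target), 25)
  expect_equal(unique(tb$ct[tb$gene == "reference"]), 18)
  expect_error(ct_table_spec(4, noise_sd = -1, seed = 1), "noise_sd")
  expect_error(ct_table_spec(-2, seed = 1), "true_fold_change")
})
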