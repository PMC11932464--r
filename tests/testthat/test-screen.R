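test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  for (s in 1:200) {
    set.seed(s)
    p <- runif(sample.int(20, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("allele-pair scoring enforces the one-SNP contract", {
  m <- cebpb_like_pfm()
  null <- calibrate_null(m, uniform_background(), 52, 500, seed = 31)
  pr <- make_allelic_pair(m, 21, 4, TRUE, seed = 41)
  expect_error(score_allele_pair(m, pr$seq_ref, pr$seq_ref, pr$snp_index,
                                 null), "exactly")
  expect_error(score_allele_pair(m, pr$seq_ref, substr(pr$seq_alt, 1, 51),
                                 pr$snp_index, null), "equal length")
  # wrong index for a real single difference
  expect_error(score_allele_pair(m, pr$seq_ref, pr$seq_alt, 1L, null),
               "exactly")
})

test_that("the sign convention marks the stronger-binding reference allele", {
  m <- cebpb_like_pfm()
  null <- calibrate_null(m, uniform_background(), 52, 1000, seed = 32)
  pr <- make_allelic_pair(m, 21, 4, TRUE, seed = 42)
  eff <- score_allele_pair(m, pr$seq_ref, pr$seq_alt, pr$snp_index, null,
                           snp_id = "rs_like")
  expect_gt(eff$dlogp, 0)
  expect_lt(eff$p_ref, eff$p_alt)
  expect_equal(eff$p_combined, min(1, 2 * min(eff$p_ref, eff$p_alt)))
  expect_gte(eff$best_rel_score, 0.95)
  expect_true(eff$congruent)
  expect_equal(eff$preferred_allele, "ref")

  # swapped roles flip the sign
  swap <- score_allele_pair(m, pr$seq_alt, pr$seq_ref, pr$snp_index, null,
                            snp_id = "rs_like")
  expect_lt(swap$dlogp, 0)
  expect_equal(swap$preferred_allele, "alt")
})

test_that("background-position SNPs stay near dlogp zero", {
  # bound frozen after a 50-seed calibration (max observed 0.93)
  m <- cebpb_like_pfm()
  null <- calibrate_null(m, uniform_background(), 52, 2000, seed = 33)
  dl <- vapply(1:25, function(s) {
    pr <- background_snp_pair(seed = 5000 + s)
    score_allele_pair(m, pr$seq_ref, pr$seq_alt, pr$snp_index, null,
                      snp_id = "bg")$dlogp
  }, numeric(1))
  expect_true(all(abs(dl) < 1.2))
  expect_lt(mean(abs(dl)), 0.5)
})

test_that("congruence requires the SNP inside a preferring column", {
  m <- cebpb_like_pfm()
  w <- build_pwm(m)
  pr <- make_allelic_pair(m, 21, 4, TRUE, seed = 43)
  hits <- scan_pwm(w, pr$seq_ref, rel_threshold = 0)
  hits <- hits[hits$strand == "+", ]
  top <- hits[which.max(hits$rel_score), ]

  # SNP outside the hit window
  out <- congruence_check(w, snp_index = 1L, top, "A", "C")
  expect_false(out$congruent)
  expect_equal(out$preferred_allele, "none")

  # SNP at the anchor column with ref = consensus base (C), alt = weak
  cc <- congruence_check(w, pr$snp_index, top, "C", "A")
  expect_true(cc$congruent)
  expect_equal(cc$preferred_allele, "ref")

  # a nearly flat column fails the preference-ratio threshold
  flatish <- pfm("flatish", matrix(c(11, 10, 1, 1,
                                     30, 2, 2, 2), nrow = 4))
  wf <- build_pwm(flatish)
  hit <- data.frame(start = 1L, strand = "+")
  ff <- congruence_check(wf, 1L, hit, "A", "C")
  expect_false(ff$congruent)
  # neither allele matching the top base also yields none
  nn <- congruence_check(w, pr$snp_index, top, "G", "T")
  expect_equal(nn$preferred_allele, "none")
})

test_that("the screen ranks deterministically and flags nothing spurious", {
  lib <- list(cebpb_like_pfm(), gfi1_like_pfm(), gc_box_pfm())
  cache <- new.env(parent = emptyenv())
  cfg <- screen_config(n_null = 500, seed = 3, null_cache = cache)
  snps <- do.call(rbind, lapply(1:4, function(k) {
    pr <- background_snp_pair(seed = 700 + k)
    data.frame(snp_id = paste0("rs_bg", k), seq_ref = pr$seq_ref,
               seq_alt = pr$seq_alt, snp_index = pr$snp_index,
               stringsAsFactors = FALSE)
  }))
  rep1 <- run_screen(snps, lib, cfg)
  expect_equal(nrow(rep1$rows), 12L)
  expect_false(any(rep1$rows$significant))
  # q-values are monotone along the sorted report
  expect_false(is.unsorted(rep1$rows$q_value))

  # permuting the input rows leaves the sorted report identical
  rep2 <- run_screen(snps[c(3, 1, 4, 2), ], lib, cfg)
  expect_equal(rep1$rows, rep2$rows)

  expect_error(run_screen(snps, list(), cfg), "nonempty")
})

test_that("a motif-destroying SNP tops the screen and is flagged", {
  lib <- list(cebpb_like_pfm(), gfi1_like_pfm(), gc_box_pfm())
  cfg <- screen_config(n_null = 1000, seed = 5,
                       null_cache = new.env(parent = emptyenv()))
  eff <- make_allelic_pair(cebpb_like_pfm(), 21, 4, TRUE, seed = 77)
  snps <- rbind(
    data.frame(snp_id = "rs_eff", seq_ref = eff$seq_ref,
               seq_alt = eff$seq_alt, snp_index = eff$snp_index,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:3, function(k) {
      pr <- background_snp_pair(seed = 800 + k)
      data.frame(snp_id = paste0("rs_bg", k), seq_ref = pr$seq_ref,
                 seq_alt = pr$seq_alt, snp_index = pr$snp_index,
                 stringsAsFactors = FALSE)
    })))
  rep <- run_screen(snps, lib, cfg)
  top <- rep$rows[1, ]
  expect_equal(top$snp_id, "rs_eff")
  expect_equal(top$tf_id, "CEBPB_synth")
  expect_true(top$significant)
  expect_true(top$congruent)

  # the raw-p pre-filter can veto the q-based flag
  cfg_strict <- screen_config(n_null = 1000, seed = 5,
                              raw_p_threshold = 1e-12,
                              null_cache = new.env(parent = emptyenv()))
  rep_strict <- run_screen(snps, lib, cfg_strict)
  expect_false(any(rep_strict$rows$significant))
})

test_that("spacing analysis finds exact arithmetic progressions", {
  res <- spacing_analysis(c(41810515, 41811942, 41813369))
  expect_equal(nrow(res$progressions), 1L)
  expect_equal(res$progressions$start_anchor, 41810515)
  expect_equal(res$progressions$common_difference, 1427)
  expect_equal(res$progressions$length, 3L)
  expect_equal(sort(res$pairwise_gaps), c(1427, 1427, 2854))

  two <- spacing_analysis(c(10, 20))
  expect_equal(nrow(two$progressions), 0L)
  expect_equal(two$pairwise_gaps, 10)

  four <- spacing_analysis(c(0, 7, 14, 21))
  expect_equal(nrow(four$progressions), 1L)
  expect_equal(four$progressions$common_difference, 7)
  expect_equal(four$progressions$length, 4L)

  expect_warning(unsorted <- spacing_analysis(c(14, 0, 7)), "sort")
  expect_equal(unsorted$progressions$common_difference, 7)
  expect_error(spacing_analysis(5), "at least 2")
})

test_that("spacing tolerance admits near-arithmetic triples", {
  res <- spacing_analysis(c(100, 200, 302), tolerance_bp = 2)
  expect_equal(nrow(res$progressions), 1L)
  expect_equal(res$progressions$length, 3L)
  none <- spacing_analysis(c(100, 200, 305), tolerance_bp = 2)
  expect_equal(nrow(none$progressions), 0L)
})
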