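test_that("PWM probabilities and log-odds follow the stated formulas", {
  p <- pfm("single", matrix(c(10, 0, 0, 0), nrow = 4))
  w <- build_pwm(p, uniform_background(), pseudocount = 0.8)
  expect_equal(unname(w$probs["A", 1]), 10.2 / 10.8, tolerance = 1e-12)
  expect_equal(unname(w$log_odds["A", 1]), log2((10.2 / 10.8) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(w$log_odds["C", 1]), log2((0.2 / 10.8) / 0.25),
               tolerance = 1e-12)

  # s_max is attained exactly by the column-wise argmax word
  m <- random_pfm(6, seed = 1)
  wm <- build_pwm(m)
  expect_equal(brute_word_score(consensus_word(m), wm$log_odds), wm$s_max,
               tolerance = 1e-12)

  flat <- pfm("flat", matrix(1, nrow = 4, ncol = 3))
  expect_error(build_pwm(flat), "degenerate matrix")
})

test_that("JASPAR and MEME parsers read counts faithfully", {
  txt <- c(">MA0001.1 TESTF",
           "A [ 3 10  0 ]",
           "C [ 2  0  1 ]",
           "G [ 4  0  9 ]",
           "T [ 1  0  0 ]",
           ">PLAIN second",
           "1 2", "3 4", "5 6", "7 8")
  pfms <- read_jaspar(text = txt)
  expect_named(pfms, c("MA0001.1", "PLAIN"))
  expect_equal(unname(pfms$MA0001.1$counts["G", 3]), 9)
  expect_equal(consensus_word(pfms$MA0001.1), "GAG")
  expect_equal(pfms$PLAIN$counts[, 1], c(A = 1, C = 3, G = 5, T = 7))

  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pfms, path)
  back <- read_jaspar(path)
  expect_equal(back$MA0001.1$counts, pfms$MA0001.1$counts)

  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF M1 factor1",
               "letter-probability matrix: alength= 4 w= 2 nsites= 10",
               "0.5 0.2 0.2 0.1",
               "0.1 0.1 0.1 0.7"), meme)
  mm <- read_meme(meme)
  expect_equal(mm$M1$counts[, 1], c(A = 5, C = 2, G = 2, T = 1))
  expect_equal(consensus_word(mm$M1), "AT")
})

test_that("scanning finds the consensus with relative score 1", {
  m <- cebpb_like_pfm()
  w <- build_pwm(m)
  sp <- motif_plant_spec(m, 21, "+", length = 60, seed = 9)
  hits <- scan_pwm(w, plant_motifs(sp), rel_threshold = 0.95)
  top <- hits[which.max(hits$rel_score), ]
  expect_equal(top$start, 21L)
  expect_equal(top$rel_score, 1.0)
  expect_error(scan_pwm(w, "ACGTNACGTTT", rel_threshold = 0),
               "invalid sequence")
})

test_that("scan hit sets mirror under reverse complement", {
  m <- random_pfm(5, seed = 3)
  w <- build_pwm(m)
  set.seed(4)
  seq <- random_dna(40)
  fwd <- scan_pwm(w, seq, rel_threshold = 0)
  rev <- scan_pwm(w, reverse_complement(seq), rel_threshold = 0)
  # same multiset of scores; a + hit at start i maps to a - hit at L-W-i+2
  expect_equal(sort(fwd$score), sort(rev$score), tolerance = 1e-12)
  L <- nchar(seq); W <- ncol(m$counts)
  fwd_plus <- fwd[fwd$strand == "+", ]
  rev_minus <- rev[rev$strand == "-", ]
  mapped <- L - W - fwd_plus$start + 2L
  expect_equal(sort(rev_minus$start), sort(mapped))
  expect_equal(rev_minus$score[order(rev_minus$start)],
               fwd_plus$score[order(mapped)], tolerance = 1e-12)
})

test_that("width-2 scanning ranks all 16 dinucleotides like brute force", {
  # untied column maxima so the consensus word is the unique rel = 1 window
  m <- pfm("w2", matrix(c(9, 2, 1, 3, 1, 7, 2, 4), nrow = 4))
  w <- build_pwm(m)
  words <- as.vector(outer(BASES, BASES, paste0))
  mine <- vapply(words, function(x) {
    h <- scan_pwm(w, x, both_strands = FALSE, rel_threshold = 0)
    h$score
  }, numeric(1))
  brute <- vapply(words, brute_word_score, numeric(1), mat = w$log_odds)
  expect_equal(mine, brute, tolerance = 1e-12)
  expect_equal(order(mine), order(brute))
  rel <- (mine - w$s_min) / (w$s_max - w$s_min)
  expect_true(all(rel >= 0 & rel <= 1 + 1e-12))
  expect_equal(sum(abs(rel - 1) < 1e-12), 1L)  # only the consensus word
})

test_that("occupancy matches its closed form and brute-force oracle", {
  m <- cebpb_like_pfm()
  cons <- consensus_word(m)
  # single consensus window at R0 = 1: the plus-strand term is exactly 0.5
  occ <- trap_affinity(cons, m, trap_params(r0_override = 1))
  rc_term <- brute_trap(cons, m$counts, 0.7, 1, 0.8) - 0.5
  expect_equal(occ, 0.5 + rc_term, tolerance = 1e-12)
  expect_gte(occ, 0.5)

  set.seed(6)
  for (width in 2:4) {
    mm <- random_pfm(width, seed = width * 11)
    prm <- trap_params()
    r0 <- exp(0.584 * width - 5.66)
    for (s in random_dna(8, n = 10)) {
      expect_equal(trap_affinity(s, mm, prm),
                   brute_trap(s, mm$counts, 0.7, r0, 0.8),
                   tolerance = 1e-12)
    }
  }
})

test_that("occupancy grows with planted sites and respects its bound", {
  m <- cebpb_like_pfm()
  base1 <- plant_motifs(motif_plant_spec(m, 31, "+", length = 200, seed = 7))
  base2 <- plant_motifs(motif_plant_spec(m, c(31, 101), c("+", "+"),
                                         length = 200, seed = 7))
  expect_gt(trap_affinity(base2, m), trap_affinity(base1, m))

  prm <- trap_params()
  r0 <- exp(0.584 * 10 - 5.66)
  L <- 200; W <- 10
  bound <- 2 * (L - W + 1) * r0 / (1 + r0)
  expect_lte(trap_affinity(base2, m, prm), bound)

  # strand symmetry is exact
  expect_equal(trap_affinity(base2, m), trap_affinity(reverse_complement(base2), m),
               tolerance = 1e-12)
})

test_that("null calibration is deterministic and p-values behave as ranks", {
  m <- gfi1_like_pfm()
  bg <- uniform_background()
  n1 <- calibrate_null(m, bg, 40, 200, seed = 21)
  n2 <- calibrate_null(m, bg, 40, 200, seed = 21)
  expect_identical(n1$occupancies, n2$occupancies)
  expect_true(all(n1$occupancies >= 0))
  expect_false(is.unsorted(n1$occupancies))

  # above every null value, below every null value, and at the median
  expect_equal(affinity_pvalue(max(n1$occupancies) + 1, n1), 1 / 201)
  expect_equal(affinity_pvalue(min(n1$occupancies) - 1, n1), 1.0)
  med_p <- affinity_pvalue(median(n1$occupancies), n1)
  expect_lt(abs(med_p - 0.5), 2 / sqrt(200))
  expect_error(calibrate_null(m, bg, 40, 50, seed = 1), "n_null")
})

test_that("order-1 backgrounds keep their marginal composition", {
  bg <- promoter_background()
  set.seed(30)
  seqs <- simulate_background_seq(bg, 500, n = 40)
  comp <- table(factor(unlist(strsplit(seqs, "")), levels = BASES))
  comp <- comp / sum(comp)
  expect_lt(abs(comp[["C"]] + comp[["G"]] - 0.56), 0.03)
  # CpG depletion: fewer CG dinucleotides than GC
  cg <- sum(unlist(gregexpr("CG", seqs, fixed = TRUE)) > 0)
  gc <- sum(unlist(gregexpr("GC", seqs, fixed = TRUE)) > 0)
  expect_lt(cg, gc)
})
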