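# Independent oracles and fixture builders shared across the test files.
# These deliberately re-derive results from first principles with naive code
# (character-level loops, exhaustive enumeration) and never call the package
# routines they check.

BASES <- c("A", "C", "G", "T")

# naive log-odds score of one word under a 4 x W matrix
brute_word_score <- function(word, mat) {
  s <- 0
  for (j in seq_len(nchar(word))) {
    s <- s + mat[match(substr(word, j, j), BASES), j]
  }
  unname(s)
}

brute_revcomp <- function(word) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(word, "")[[1]]]), collapse = "")
}

# all windows on both strands with scores, plus-strand start coordinates
brute_scan <- function(log_odds, seq) {
  W <- ncol(log_odds)
  L <- nchar(seq)
  rows <- list()
  for (i in seq_len(L - W + 1)) {
    word <- substr(seq, i, i + W - 1)
    rows[[length(rows) + 1]] <- data.frame(
      start = i, strand = "+", score = brute_word_score(word, log_odds))
    rows[[length(rows) + 1]] <- data.frame(
      start = i, strand = "-",
      score = brute_word_score(brute_revcomp(word), log_odds))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), ]
}

# naive occupancy: per-window mismatch energies from raw counts
brute_trap <- function(seq, counts, lambda, r0, pc) {
  W <- ncol(counts)
  cmax <- apply(counts, 2, max)
  occ_of <- function(word) {
    e <- 0
    for (j in seq_len(W)) {
      b <- match(substr(word, j, j), BASES)
      e <- e + log((cmax[j] + pc) / (counts[b, j] + pc)) / lambda
    }
    r0 * exp(-e) / (1 + r0 * exp(-e))
  }
  total <- 0
  for (i in seq_len(nchar(seq) - W + 1)) {
    word <- substr(seq, i, i + W - 1)
    total <- total + occ_of(word) + occ_of(brute_revcomp(word))
  }
  unname(total)
}

# textbook BH step-up computed from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, (m / seq_len(m)) * p[o])
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# all 3-subsets of anchors forming an arithmetic progression within tol
brute_ap3 <- function(anchors, tol = 0) {
  anchors <- sort(unique(anchors))
  n <- length(anchors)
  out <- list()
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      d1 <- anchors[j] - anchors[i]
      d2 <- anchors[k] - anchors[j]
      if (abs(d1 - d2) <= tol) {
        out[[length(out) + 1]] <- anchors[c(i, j, k)]
      }
    }
  }
  out
}

# the 3-term sub-progressions implied by a spacing_analysis result
triples_from_progressions <- function(res) {
  out <- list()
  if (!nrow(res$progressions)) return(out)
  for (r in seq_len(nrow(res$progressions))) {
    start <- res$progressions$start_anchor[r]
    d <- res$progressions$common_difference[r]
    len <- res$progressions$length[r]
    members <- start + d * (seq_len(len) - 1)
    if (len >= 3) {
      for (i in 1:(len - 2)) {
        out[[length(out) + 1]] <- members[i:(i + 2)]
      }
    }
  }
  out
}

random_pfm <- function(width, seed) {
  set.seed(seed)
  pfm(paste0("rand_w", width, "_s", seed),
      matrix(sample(0:9, 4 * width, replace = TRUE) + 0.5, nrow = 4))
}

random_dna <- function(len, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# a background allele pair differing at one uniformly chosen position
background_snp_pair <- function(seed, len = 52,
                                bg = uniform_background()) {
  set.seed(seed)
  ref <- simulate_background_seq(bg, len)
  i <- sample.int(len, 1)
  ch <- strsplit(ref, "")[[1]]
  alt <- ch
  alt[i] <- sample(setdiff(BASES, ch[i]), 1)
  list(seq_ref = ref, seq_alt = paste(alt, collapse = ""), snp_index = i)
}

two_site_panel <- function(x, y) {
  haplotype_panel(cbind(x, y),
                  data.frame(chrom = "chr1", pos = c(100L, 200L),
                             ref = "A", alt = "C", id = c("sA", "sB"),
                             stringsAsFactors = FALSE))
}
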