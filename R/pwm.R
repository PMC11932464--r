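#' Build a position weight matrix from a PFM
#'
#' Column probabilities use a background-distributed pseudocount,
#' p(b,j) = (n(b,j) + pc * bg(b)) / (N_j + pc), and log-odds are
#' log2(p(b,j) / bg(b)). Per-column extremes and their sums (s_min, s_max)
#' support the relative score (score - s_min) / (s_max - s_min), which is 1
#' exactly for the consensus word. The anchor column defaults to the column
#' with maximal information content relative to the background; scan hits
#' report the sequence coordinate of that column as `anchor_pos`, the anchor
#' used when measuring distances between motif occurrences.
#'
#' @param pfm a [pfm()].
#' @param bg a [background_model()]; its marginal base frequencies are used.
#' @param pseudocount total pseudocount per column, distributed by `bg`.
#' @param anchor_col override for the anchor column (1..W).
#' @return an object of class `pwm`.
#' @export
build_pwm <- function(pfm, bg = uniform_background(), pseudocount = 0.8,
                      anchor_col = NULL) {
  stopifnot(inherits(pfm, "pfm"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("`pseudocount` must be > 0", call. = FALSE)
  }
  bgf <- background_freqs(bg)
  counts <- pfm$counts
  totals <- colSums(counts)
  probs <- sweep(counts + pseudocount * bgf, 2L, totals + pseudocount, "/")
  log_odds <- log2(probs / bgf)
  col_max <- apply(log_odds, 2L, max)
  col_min <- apply(log_odds, 2L, min)
  s_max <- sum(col_max)
  s_min <- sum(col_min)
  if (s_max - s_min < 1e-12) {
    stop("degenerate matrix: all columns flat, relative score undefined",
         call. = FALSE)
  }
  ic <- colSums(probs * log2(probs / bgf))
  if (is.null(anchor_col)) {
    anchor_col <- which.max(ic)
  } else {
    anchor_col <- as.integer(anchor_col)
    if (anchor_col < 1L || anchor_col > ncol(counts)) {
      stop("`anchor_col` outside motif", call. = FALSE)
    }
  }
  structure(list(tf_id = pfm$tf_id, source = pfm, bg = bg,
                 pseudocount = pseudocount, probs = probs,
                 log_odds = log_odds, col_max = col_max, col_min = col_min,
                 s_max = s_max, s_min = s_min, anchor_col = anchor_col),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$tf_id, "  width ", ncol(x$log_odds),
      "  score range [", format(x$s_min, digits = 4), ", ",
      format(x$s_max, digits = 4), "]  anchor column ", x$anchor_col,
      "\n", sep = "")
  invisible(x)
}

# Score every window of `codes` (integer-encoded sequence) under a 4 x W
# scoring matrix; returns the vector of window scores, one per start.
window_scores <- function(codes, mat) {
  W <- ncol(mat)
  n_win <- length(codes) - W + 1L
  s <- numeric(n_win)
  for (j in seq_len(W)) {
    s <- s + mat[codes[j:(j + n_win - 1L)], j]
  }
  s
}

# Scoring matrix for minus-strand windows reported in plus-strand
# coordinates: row b, column j scores the complement of b at motif
# column W - j + 1.
revcomp_matrix <- function(mat) {
  W <- ncol(mat)
  out <- mat[c(4L, 3L, 2L, 1L), W:1, drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Scan a sequence with a PWM
#'
#' Reports every window whose relative score reaches `rel_threshold`, on the
#' plus strand and (by default) the minus strand. Minus-strand windows are
#' scored on the reverse complement but reported with plus-strand start
#' coordinates. Ties are kept.
#'
#' @param pwm a [build_pwm()] object.
#' @param seq uppercase ACGT string, length >= motif width.
#' @param both_strands scan the minus strand too.
#' @param rel_threshold minimum relative score in `[0, 1]`.
#' @return data.frame with columns tf_id, start (1-based), strand, score,
#'   rel_score, anchor_pos; ordered by start, then strand.
#' @export
scan_pwm <- function(pwm, seq, both_strands = TRUE, rel_threshold = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  stopifnot_flag(both_strands, "both_strands")
  codes <- encode_dna(seq)
  W <- ncol(pwm$log_odds)
  if (length(codes) < W) {
    stop("sequence shorter than motif width", call. = FALSE)
  }
  rng <- pwm$s_max - pwm$s_min
  n_win <- length(codes) - W + 1L
  starts <- seq_len(n_win)

  s_plus <- window_scores(codes, pwm$log_odds)
  rel_plus <- (s_plus - pwm$s_min) / rng
  res <- data.frame(tf_id = pwm$tf_id, start = starts, strand = "+",
                    score = s_plus, rel_score = rel_plus,
                    anchor_pos = starts + pwm$anchor_col - 1L,
                    stringsAsFactors = FALSE)
  if (both_strands) {
    s_minus <- window_scores(codes, revcomp_matrix(pwm$log_odds))
    rel_minus <- (s_minus - pwm$s_min) / rng
    res_minus <- data.frame(tf_id = pwm$tf_id, start = starts, strand = "-",
                            score = s_minus, rel_score = rel_minus,
                            anchor_pos = starts + W - pwm$anchor_col,
                            stringsAsFactors = FALSE)
    res <- rbind(res, res_minus)
  }
  res <- res[res$rel_score >= rel_threshold - 1e-9, , drop = FALSE]
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
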