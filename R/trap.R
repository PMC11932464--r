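#' Parameters of the biophysical occupancy (TRAP-type) affinity model
#'
#' The model assigns every sequence window a mismatch energy
#' E_i = (1/lambda) * sum_j ln((n(b_max,j) + pc) / (n(b_ij,j) + pc)),
#' where n(b,j) are PFM counts, b_max the column consensus base and pc a
#' pseudocount, and sums Fermi-type occupancy terms
#' R0 exp(-E_i) / (1 + R0 exp(-E_i)) over all windows on both strands.
#' R0 scales with motif width W as exp(ln_r0_slope * W + ln_r0_intercept)
#' unless overridden.
#'
#' @param lambda energy scale (> 0); default 0.7.
#' @param ln_r0_slope per-column slope of ln R0; default 0.584.
#' @param ln_r0_intercept intercept of ln R0; default -5.66.
#' @param r0_override fixed R0, bypassing the width scaling.
#' @return an object of class `trap_params`.
#' @export
trap_params <- function(lambda = 0.7, ln_r0_slope = 0.584,
                        ln_r0_intercept = -5.66, r0_override = NULL) {
  if (!is.numeric(lambda) || lambda <= 0) stop("`lambda` must be > 0", call. = FALSE)
  if (!is.null(r0_override) && (!is.numeric(r0_override) || r0_override <= 0)) {
    stop("`r0_override` must be > 0", call. = FALSE)
  }
  structure(list(lambda = lambda, ln_r0_slope = ln_r0_slope,
                 ln_r0_intercept = ln_r0_intercept,
                 r0_override = r0_override),
            class = "trap_params")
}

# Precompute the 4 x W per-position energy contributions (natural log) and
# R0 for a motif; shared by trap_affinity and calibrate_null.
trap_energy_model <- function(pfm, params, pseudocount) {
  stopifnot(inherits(pfm, "pfm"), inherits(params, "trap_params"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("`pseudocount` must be > 0", call. = FALSE)
  }
  counts <- pfm$counts
  W <- ncol(counts)
  cmax <- apply(counts, 2L, max)
  emat <- log(sweep(1 / (counts + pseudocount), 2L, cmax + pseudocount, "*")) /
    params$lambda
  r0 <- if (is.null(params$r0_override)) {
    exp(params$ln_r0_slope * W + params$ln_r0_intercept)
  } else {
    params$r0_override
  }
  list(emat = emat, emat_rc = revcomp_matrix(emat), r0 = r0, W = W)
}

trap_occupancy_codes <- function(codes, model) {
  if (length(codes) < model$W) {
    stop("sequence shorter than motif width", call. = FALSE)
  }
  e <- c(window_scores(codes, model$emat),
         window_scores(codes, model$emat_rc))
  x <- model$r0 * exp(-e)
  sum(x / (1 + x))
}

#' Expected occupancy of a motif on a sequence
#'
#' @param seq uppercase ACGT string.
#' @param pfm a [pfm()].
#' @param params a [trap_params()].
#' @param pseudocount pseudocount added to PFM counts in the energy term.
#' @return nonnegative expected occupancy (sum over windows, both strands).
#' @export
trap_affinity <- function(seq, pfm, params = trap_params(), pseudocount = 0.8) {
  model <- trap_energy_model(pfm, params, pseudocount)
  trap_occupancy_codes(encode_dna(seq), model)
}

#' Calibrate an empirical occupancy null distribution
#'
#' Draws `n_null` background sequences of length `seq_len` from `bg`,
#' computes the motif occupancy of each, and stores the sorted values.
#' Affinity p-values for real sequences are then empirical tail
#' probabilities against this null.
#'
#' @param pfm a [pfm()].
#' @param bg a [background_model()].
#' @param seq_len length of the null sequences (use the length of the
#'   sequences that will be tested).
#' @param n_null number of null draws (>= 100).
#' @param seed RNG seed; identical seed gives an identical null.
#' @param params a [trap_params()].
#' @param pseudocount energy pseudocount, as in [trap_affinity()].
#' @return an object of class `null_distribution`.
#' @export
calibrate_null <- function(pfm, bg, seq_len, n_null, seed,
                           params = trap_params(), pseudocount = 0.8) {
  n_null <- as.integer(n_null)
  if (n_null < 100L) stop("`n_null` must be >= 100", call. = FALSE)
  model <- trap_energy_model(pfm, params, pseudocount)
  if (seq_len < model$W) stop("`seq_len` shorter than motif width", call. = FALSE)
  seqs <- with_seed(seed, simulate_background_seq(bg, seq_len, n_null))
  occ <- vapply(seqs, function(s) trap_occupancy_codes(encode_dna(s), model),
                numeric(1), USE.NAMES = FALSE)
  structure(list(occupancies = sort(occ), n = n_null, seq_len = seq_len,
                 tf_id = pfm$tf_id, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$tf_id, "  n = ", x$n,
      "  seq_len = ", x$seq_len, "  occupancy range [",
      format(min(x$occupancies), digits = 3), ", ",
      format(max(x$occupancies), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Empirical affinity p-value
#'
#' p = (1 + #\{null >= occupancy\}) / (n_null + 1); the +1 correction keeps
#' p in (0, 1] and makes the p-values valid (super-uniform) under the null.
#'
#' @param occupancy occupancy value(s) from [trap_affinity()].
#' @param null a [calibrate_null()] object.
#' @return p-value(s) in (0, 1].
#' @export
affinity_pvalue <- function(occupancy, null) {
  stopifnot(inherits(null, "null_distribution"))
  vapply(occupancy, function(o) {
    (1 + sum(null$occupancies >= o)) / (null$n + 1)
  }, numeric(1))
}
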