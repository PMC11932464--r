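#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min_{k >= i} (m/k) p_(k) on the sorted
#' p-values, mapped back to the input order and capped at 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in input order; empty input gives an empty vector.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Screen configuration
#'
#' @param bg background model for null calibration.
#' @param params [trap_params()] of the affinity model.
#' @param pseudocount energy/PWM pseudocount.
#' @param n_null null-distribution size per (motif, sequence length).
#' @param seed base seed; per-motif null seeds are derived from it.
#' @param q_threshold BH q-value cut for flagging rows.
#' @param raw_p_threshold optional raw p_combined pre-filter (e.g. 5e-6,
#'   the exploratory screen cut); NULL disables it.
#' @param min_pref_ratio probability ratio required for motif congruence.
#' @param null_cache optional environment for reusing calibrated nulls
#'   across calls (keyed by tf_id and sequence length).
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(bg = uniform_background(), params = trap_params(),
                          pseudocount = 0.8, n_null = 1000L, seed = 1L,
                          q_threshold = 0.05, raw_p_threshold = NULL,
                          min_pref_ratio = 2, null_cache = NULL) {
  structure(list(bg = bg, params = params, pseudocount = pseudocount,
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 q_threshold = q_threshold,
                 raw_p_threshold = raw_p_threshold,
                 min_pref_ratio = min_pref_ratio,
                 null_cache = if (is.null(null_cache)) new.env(parent = emptyenv())
                              else null_cache),
            class = "screen_config")
}

# Fetch (or calibrate and cache) the null for one motif at one sequence
# length. The null seed is derived deterministically from the config seed
# and the motif index so that every motif gets its own stream.
screen_null <- function(pfm, seq_len, config, motif_index) {
  key <- paste0(pfm$tf_id, "@", seq_len)
  cache <- config$null_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  null <- calibrate_null(pfm, config$bg, seq_len, config$n_null,
                         seed = config$seed * 1000 + motif_index,
                         params = config$params,
                         pseudocount = config$pseudocount)
  cache[[key]] <- null
  null
}

#' Score one allele pair for one motif
#'
#' Computes per-allele affinity p-values against the supplied null, the
#' log10 p difference (positive when the reference allele binds more
#' strongly), a Bonferroni-combined p over the two alleles
#' (2 min(p_ref, p_alt), capped at 1), the best relative PWM score of any
#' scan hit overlapping the SNP on either allele, and the motif-congruence
#' call at that hit.
#'
#' @param pfm a [pfm()].
#' @param seq_ref,seq_alt equal-length ACGT strings differing at exactly
#'   one position.
#' @param snp_index 1-based position of the difference.
#' @param null a [calibrate_null()] object matching the sequence length.
#' @param params a [trap_params()].
#' @param pseudocount energy/PWM pseudocount.
#' @param min_pref_ratio congruence probability-ratio threshold.
#' @param snp_id identifier carried into the result row.
#' @param pwm optional prebuilt [build_pwm()] for the same PFM.
#' @return one-row data.frame (an allele-effect record): tf_id, snp_id,
#'   p_ref, p_alt, p_combined, dlogp, best_rel_score, congruent,
#'   preferred_allele.
#' @export
score_allele_pair <- function(pfm, seq_ref, seq_alt, snp_index, null,
                              params = trap_params(), pseudocount = 0.8,
                              min_pref_ratio = 2, snp_id = NA_character_,
                              pwm = NULL) {
  if (nchar(seq_ref) != nchar(seq_alt)) {
    stop("allele sequences must have equal length", call. = FALSE)
  }
  cr <- encode_dna(seq_ref)
  ca <- encode_dna(seq_alt)
  diffs <- which(cr != ca)
  if (length(diffs) != 1L || diffs != snp_index) {
    stop("sequences must differ at exactly `snp_index` and nowhere else",
         call. = FALSE)
  }
  if (!is.null(null) && null$seq_len != length(cr)) {
    stop("null distribution was calibrated for length ", null$seq_len,
         ", sequences have length ", length(cr), call. = FALSE)
  }
  p_ref <- affinity_pvalue(trap_affinity(seq_ref, pfm, params, pseudocount),
                           null)
  p_alt <- affinity_pvalue(trap_affinity(seq_alt, pfm, params, pseudocount),
                           null)
  dlogp <- log10(p_alt) - log10(p_ref)
  p_combined <- min(1, 2 * min(p_ref, p_alt))
  if (is.null(pwm)) pwm <- build_pwm(pfm, pseudocount = pseudocount)
  W <- ncol(pwm$log_odds)
  best <- NULL
  best_rel <- 0
  for (s in list(seq_ref, seq_alt)) {
    hits <- scan_pwm(pwm, s, both_strands = TRUE, rel_threshold = 0)
    hits <- hits[hits$start <= snp_index &
                   snp_index <= hits$start + W - 1L, , drop = FALSE]
    if (nrow(hits)) {
      top <- hits[which.max(hits$rel_score), ]
      if (top$rel_score > best_rel) {
        best_rel <- top$rel_score
        best <- top
      }
    }
  }
  cc <- congruence_check(pwm, snp_index, best,
                         ref_base = DNA_BASES[cr[snp_index]],
                         alt_base = DNA_BASES[ca[snp_index]],
                         min_pref_ratio = min_pref_ratio)
  data.frame(tf_id = pfm$tf_id, snp_id = snp_id, p_ref = p_ref,
             p_alt = p_alt, p_combined = p_combined, dlogp = dlogp,
             best_rel_score = best_rel, congruent = cc$congruent,
             preferred_allele = cc$preferred_allele,
             stringsAsFactors = FALSE)
}

#' Check congruence of a SNP with a motif hit
#'
#' The SNP is congruent with the motif when it falls inside the hit window
#' and the PWM column at that offset clearly prefers one of the two SNP
#' alleles: the column's top base matches one allele and its probability
#' exceeds the other allele's probability by at least `min_pref_ratio`.
#' Minus-strand hits are assessed on the complemented alleles.
#'
#' @param pwm a [build_pwm()] object.
#' @param snp_index 1-based SNP position in the scanned sequence.
#' @param hit one row of a [scan_pwm()] result (or NULL).
#' @param ref_base,alt_base the two SNP alleles (plus-strand bases).
#' @param min_pref_ratio probability ratio threshold (default 2).
#' @return list with `congruent` (logical) and `preferred_allele`
#'   ("ref", "alt" or "none").
#' @export
congruence_check <- function(pwm, snp_index, hit, ref_base, alt_base,
                             min_pref_ratio = 2) {
  none <- list(congruent = FALSE, preferred_allele = "none")
  if (is.null(hit) || !nrow(hit)) return(none)
  W <- ncol(pwm$log_odds)
  if (snp_index < hit$start || snp_index > hit$start + W - 1L) return(none)
  col <- if (hit$strand == "+") {
    snp_index - hit$start + 1L
  } else {
    W - (snp_index - hit$start)
  }
  probs <- pwm$probs[, col]
  comp <- function(b) unname(DNA_COMPLEMENT[b])
  a_ref <- if (hit$strand == "+") ref_base else comp(ref_base)
  a_alt <- if (hit$strand == "+") alt_base else comp(alt_base)
  top <- DNA_BASES[which.max(probs)]
  preferred <- if (top == a_ref) "ref" else if (top == a_alt) "alt" else "none"
  if (preferred == "none") return(none)
  other <- if (preferred == "ref") a_alt else a_ref
  ratio <- probs[top] / probs[other]
  if (ratio >= min_pref_ratio) {
    list(congruent = TRUE, preferred_allele = preferred)
  } else {
    none
  }
}

#' Run the allele-differential TF-binding screen
#'
#' Scores every motif against every allele pair, BH-adjusts the combined
#' p-values across all motif x SNP tests, and ranks rows by q-value, then
#' |dlogp| (descending), then tf_id and snp_id for full determinism. Rows
#' with q below the configured threshold (and, when set, raw p_combined
#' below the pre-filter) are flagged significant. Null distributions are
#' calibrated once per (motif, sequence length) and reused.
#'
#' @param snps data.frame with columns snp_id, seq_ref, seq_alt, snp_index.
#' @param pfm_library nonempty list of [pfm()] objects.
#' @param config a [screen_config()].
#' @return object of class `screen_report`: `rows` (allele-effect records
#'   with q and significant columns), `significance_threshold`, `n_tests`.
#' @export
run_screen <- function(snps, pfm_library, config = screen_config()) {
  if (inherits(pfm_library, "pfm")) pfm_library <- list(pfm_library)
  if (!length(pfm_library)) stop("`pfm_library` must be nonempty", call. = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "seq_ref", "seq_alt", "snp_index")
  if (!all(need %in% names(snps)) || !nrow(snps)) {
    stop("`snps` must be a nonempty data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  rows <- vector("list", length(pfm_library) * nrow(snps))
  k <- 0L
  for (m in seq_along(pfm_library)) {
    p <- pfm_library[[m]]
    pwm <- build_pwm(p, bg = config$bg, pseudocount = config$pseudocount)
    for (s in seq_len(nrow(snps))) {
      null <- screen_null(p, nchar(snps$seq_ref[s]), config, m)
      k <- k + 1L
      rows[[k]] <- score_allele_pair(
        p, snps$seq_ref[s], snps$seq_alt[s], snps$snp_index[s], null,
        params = config$params, pseudocount = config$pseudocount,
        min_pref_ratio = config$min_pref_ratio, snp_id = snps$snp_id[s],
        pwm = pwm)
    }
  }
  rows <- do.call(rbind, rows)
  rows$q_value <- bh_adjust(rows$p_combined)
  rows$significant <- rows$q_value < config$q_threshold
  if (!is.null(config$raw_p_threshold)) {
    rows$significant <- rows$significant &
      rows$p_combined < config$raw_p_threshold
  }
  ord <- order(rows$q_value, -abs(rows$dlogp), rows$tf_id, rows$snp_id)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows, significance_threshold = config$q_threshold,
                 n_tests = nrow(rows)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", x$n_tests, " motif x SNP tests, ",
      sum(x$rows$significant), " flagged at q < ",
      x$significance_threshold, "\n", sep = "")
  print(utils::head(x$rows, 10))
  invisible(x)
}

#' Write a screen report as TSV
#'
#' @param report a [run_screen()] result.
#' @param path output path.
#' @export
write_screen_tsv <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  write.table(report$rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
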