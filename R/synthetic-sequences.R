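#' Specification for motif-planted synthetic sequences
#'
#' Describes a background sequence of a given length with motif consensus
#' words written verbatim at chosen positions and strands. Planted windows
#' must lie fully inside the sequence and may not overlap.
#'
#' @param motif a [pfm()]; its consensus word is planted.
#' @param positions integer vector of 1-based start coordinates.
#' @param strands character vector of "+" / "-" matching `positions`.
#' @param background a [background_model()] for the unplanted positions.
#' @param length sequence length in bp.
#' @param seed RNG seed for the background draw.
#' @return an object of class `motif_plant_spec`.
#' @export
motif_plant_spec <- function(motif, positions = integer(), strands = NULL,
                             background = uniform_background(), length, seed) {
  stopifnot(inherits(motif, "pfm"), inherits(background, "background_model"))
  length <- as.integer(length)
  positions <- as.integer(positions)
  if (is.null(strands)) strands <- rep("+", base::length(positions))
  if (base::length(strands) != base::length(positions)) {
    stop("`strands` must match `positions`", call. = FALSE)
  }
  if (!all(strands %in% c("+", "-"))) {
    stop("strands must be '+' or '-'", call. = FALSE)
  }
  W <- motif_width(motif)
  if (W > length) stop("motif wider than sequence", call. = FALSE)
  if (base::length(positions)) {
    if (any(positions < 1L) || any(positions + W - 1L > length)) {
      stop("planted windows must lie fully inside [1, length]", call. = FALSE)
    }
    o <- order(positions)
    p <- positions[o]
    if (any(p[-1L] - p[-base::length(p)] < W)) {
      stop("planted windows may not overlap", call. = FALSE)
    }
  }
  structure(list(motif = motif, positions = positions, strands = strands,
                 background = background, length = length,
                 seed = as.integer(seed)),
            class = "motif_plant_spec")
}

#' Generate a background sequence with planted motif consensus sites
#'
#' At each planted position the motif consensus (column-wise argmax base,
#' reverse-complemented on the minus strand) is written verbatim; every
#' other position is drawn from the background model under `spec$seed`.
#'
#' @param spec a [motif_plant_spec()].
#' @return uppercase ACGT string of length `spec$length`.
#' @export
plant_motifs <- function(spec) {
  stopifnot(inherits(spec, "motif_plant_spec"))
  base_seq <- with_seed(spec$seed,
                        simulate_background_seq(spec$background, spec$length))
  chars <- strsplit(base_seq, "", fixed = TRUE)[[1L]]
  cons <- consensus_word(spec$motif)
  W <- motif_width(spec$motif)
  for (k in seq_along(spec$positions)) {
    word <- if (spec$strands[k] == "+") cons else reverse_complement(cons)
    chars[spec$positions[k]:(spec$positions[k] + W - 1L)] <-
      strsplit(word, "", fixed = TRUE)[[1L]]
  }
  paste(chars, collapse = "")
}

#' Ground-truth intervals of the planted motifs
#'
#' @param spec a [motif_plant_spec()].
#' @param chrom chromosome/sequence name for the intervals.
#' @return a [genomic_intervals()] data.frame (0-based half-open), one row
#'   per plant, labelled `motif:<tf_id>`.
#' @export
planted_truth_intervals <- function(spec, chrom = "synthetic") {
  stopifnot(inherits(spec, "motif_plant_spec"))
  W <- motif_width(spec$motif)
  genomic_intervals(chrom = rep(chrom, length(spec$positions)),
                    start = spec$positions - 1L,
                    end = spec$positions - 1L + W,
                    label = rep(paste0("motif:", spec$motif$tf_id),
                                length(spec$positions)),
                    strand = spec$strands)
}

#' Construct an allelic sequence pair around one motif column
#'
#' Emulates the probe design used for allele-specific binding assays: the
#' motif consensus word flanked by `flank` random background bases on each
#' side, with one motif column carrying either its consensus base or its
#' minimum-probability base. With `ref_is_consensus = TRUE` the reference
#' sequence carries the consensus base and the alternative carries the
#' weakest base (a motif-destroying SNP); with `FALSE` the roles swap.
#'
#' @param motif a [pfm()].
#' @param flank flanking bases on each side (default 21, the usual probe
#'   flank length).
#' @param snp_offset_in_motif 0-based column offset of the SNP inside the
#'   motif (0 <= offset < width).
#' @param ref_is_consensus logical; see above.
#' @param seed RNG seed for the flanks.
#' @param background a [background_model()] for the flanks.
#' @return list with `seq_ref`, `seq_alt` (equal-length strings differing at
#'   exactly one position) and `snp_index` (1-based).
#' @export
make_allelic_pair <- function(motif, flank = 21L, snp_offset_in_motif,
                              ref_is_consensus = TRUE, seed,
                              background = uniform_background()) {
  stopifnot(inherits(motif, "pfm"))
  stopifnot_flag(ref_is_consensus, "ref_is_consensus")
  W <- motif_width(motif)
  off <- as.integer(snp_offset_in_motif)
  if (off < 0L || off >= W) {
    stop("`snp_offset_in_motif` must satisfy 0 <= offset < width",
         call. = FALSE)
  }
  col <- motif$counts[, off + 1L]
  if (diff(range(col)) == 0) {
    stop("non-informative column: all bases equally frequent at offset ",
         off, call. = FALSE)
  }
  cons_base <- DNA_BASES[which.max(col)]
  weak_base <- DNA_BASES[which.min(col)]
  flank <- as.integer(flank)
  flanks <- with_seed(seed,
                      simulate_background_seq(background, 2L * flank + 2L))
  # one draw, split deterministically into left and right flank
  fl <- substr(flanks, 1L, flank)
  fr <- substr(flanks, flank + 1L, 2L * flank)
  cons <- strsplit(consensus_word(motif), "", fixed = TRUE)[[1L]]
  snp_index <- flank + off + 1L
  mk <- function(base_at_snp) {
    word <- cons
    word[off + 1L] <- base_at_snp
    paste0(fl, paste(word, collapse = ""), fr)
  }
  if (ref_is_consensus) {
    list(seq_ref = mk(cons_base), seq_alt = mk(weak_base),
         snp_index = snp_index)
  } else {
    list(seq_ref = mk(weak_base), seq_alt = mk(cons_base),
         snp_index = snp_index)
  }
}
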