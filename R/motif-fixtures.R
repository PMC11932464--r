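#' Synthetic motif matrices for simulation and examples
#'
#' These PFMs are constructed in code, not downloaded: they are synthetic
#' stand-ins with the qualitative shape of the real factors' motifs
#' (consensus word, width, an information-rich anchor column) and are used
#' by the simulation drivers and tests. They are NOT the curated database
#' matrices; analyses of real data should load a motif library with
#' [read_jaspar()] or [read_meme()].
#'
#' `cebpb_like_pfm()` is a bZIP-style motif around the TTGCACAA half-site
#' pair (consensus ATTGCACAAT) whose central C column is nearly
#' invariant -- the anchor column used when measuring distances between
#' occurrences. The consensus is deliberately non-palindromic so an
#' anchor-destroying SNP cannot be rescued by the reverse strand.
#' `gfi1_like_pfm()` and `gc_box_pfm()` are moderate-information decoys.
#'
#' @param sharp_count count of the dominant base in the near-invariant
#'   anchor column.
#' @return a [pfm()].
#' @export
cebpb_like_pfm <- function(sharp_count = 5000) {
  consensus <- strsplit("ATTGCACAAT", "")[[1L]]
  W <- length(consensus)
  counts <- matrix(4, nrow = 4L, ncol = W, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(W)) counts[consensus[j], j] <- 48
  anchor <- 5L  # the central C
  counts[, anchor] <- 0.5
  counts[consensus[anchor], anchor] <- sharp_count
  pfm("CEBPB_synth", counts, name = "CEBPB-like (synthetic)")
}

#' @rdname cebpb_like_pfm
#' @export
gfi1_like_pfm <- function() {
  consensus <- strsplit("AAATCACT", "")[[1L]]
  counts <- matrix(5, nrow = 4L, ncol = length(consensus),
                   dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 35
  pfm("GFI1_synth", counts, name = "GFI-1-like (synthetic)")
}

#' @rdname cebpb_like_pfm
#' @export
gc_box_pfm <- function() {
  consensus <- strsplit("GGGGCGGG", "")[[1L]]
  counts <- matrix(6, nrow = 4L, ncol = length(consensus),
                   dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 32
  pfm("GCBOX_synth", counts, name = "GC-box-like (synthetic)")
}
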