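#' Read and write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping sequences as plain named uppercase
#' character vectors, which is what the scanners consume.
#'
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read allele sequence pairs from FASTA
#'
#' Expects records named `<id>_ref` and `<id>_alt`. The SNP position of a
#' pair is inferred as the single position where the two sequences differ.
#'
#' @param path FASTA path.
#' @return data.frame with columns snp_id, seq_ref, seq_alt, snp_index,
#'   ready for [run_screen()].
#' @export
read_allele_pairs <- function(path) {
  seqs <- read_fasta(path)
  refs <- grep("_ref$", names(seqs), value = TRUE)
  ids <- sub("_ref$", "", refs)
  missing_alt <- !paste0(ids, "_alt") %in% names(seqs)
  if (any(missing_alt)) {
    stop("missing _alt record(s) for: ",
         paste(ids[missing_alt], collapse = ", "), call. = FALSE)
  }
  rows <- lapply(ids, function(id) {
    r <- seqs[[paste0(id, "_ref")]]
    a <- seqs[[paste0(id, "_alt")]]
    if (nchar(r) != nchar(a)) {
      stop("allele sequences of ", id, " differ in length", call. = FALSE)
    }
    d <- which(encode_dna(r) != encode_dna(a))
    if (length(d) != 1L) {
      stop("allele sequences of ", id, " must differ at exactly one ",
           "position (found ", length(d), ")", call. = FALSE)
    }
    data.frame(snp_id = id, seq_ref = r, seq_alt = a, snp_index = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
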