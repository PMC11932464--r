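#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnorm runif t.test p.adjust aggregate
#' @importFrom utils read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Run code with a temporary RNG state seeded at `seed`; the caller's RNG
# stream is untouched, so generators are reproducible in isolation.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  # derived seeds (base * offset) can exceed .Machine$integer.max; fold
  # them back into the valid range deterministically
  seed <- abs(seed) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; published allele frequencies are
#' conventionally rounded half-up (0.3975 prints as 0.398), so reporting
#' helpers use this variant.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.3975, 3)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # kill binary representation error (e.g. 0.3975 * 1000 = 397.4999...)
  # before the half-up step
  y <- round(abs(x) * scale, 9)
  sign(x) * floor(y + 0.5) / scale
}

# Encode an uppercase ACGT string as integers 1..4; reject anything else.
encode_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  codes <- match(chars, DNA_BASES)
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("invalid sequence: non-ACGT character(s) ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  codes
}

decode_dna <- function(codes) paste(DNA_BASES[codes], collapse = "")

#' Reverse complement of a DNA string
#'
#' @param seq uppercase ACGT string.
#' @return the reverse complement, also uppercase ACGT.
#' @export
reverse_complement <- function(seq) {
  codes <- encode_dna(seq)
  decode_dna(rev(5L - codes))
}

stopifnot_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be TRUE or FALSE", call. = FALSE)
  }
  invisible(x)
}
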