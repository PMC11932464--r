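#' Position frequency matrices
#'
#' A PFM stores per-column base counts (rows A,C,G,T) for one transcription
#' factor motif. Counts may be real-valued (JASPAR matrices often are).
#'
#' @param tf_id identifier of the factor/matrix (e.g. a JASPAR accession).
#' @param counts 4 x W nonnegative numeric matrix; rows in A,C,G,T order.
#' @param name optional human-readable factor name.
#' @return an object of class `pfm`.
#' @export
pfm <- function(tf_id, counts, name = tf_id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("`counts` must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(counts) < 1L) stop("motif width must be >= 1", call. = FALSE)
  if (any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be nonnegative and non-missing", call. = FALSE)
  }
  if (any(colSums(counts) <= 0)) {
    stop("every PFM column must have a positive total", call. = FALSE)
  }
  rownames(counts) <- DNA_BASES
  colnames(counts) <- NULL
  structure(list(tf_id = as.character(tf_id), name = as.character(name),
                 counts = counts),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> ", x$tf_id, if (!identical(x$name, x$tf_id)) paste0(" (", x$name, ")"),
      "  width ", ncol(x$counts), "  consensus ", consensus_word(x), "\n", sep = "")
  print(round(x$counts, 2))
  invisible(x)
}

motif_width <- function(x) {
  counts <- if (inherits(x, "pfm")) x$counts else x$source$counts
  ncol(counts)
}

#' Consensus word of a motif
#'
#' Column-wise argmax base; ties broken by fixed base order A<C<G<T so the
#' consensus is reproducible.
#'
#' @param pfm a `pfm`.
#' @return uppercase string of width W.
#' @export
consensus_word <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  decode_dna(apply(pfm$counts, 2L, which.max))
}

#' Information content of a motif (bits)
#'
#' Per-column 2 - H(p) with p the column base probabilities (no pseudocount),
#' summed over columns. Degenerate columns contribute 0.
#'
#' @param pfm a `pfm`.
#' @param per_column return the per-column vector instead of the total.
#' @return total bits, or per-column vector.
#' @export
information_content <- function(pfm, per_column = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  p <- sweep(pfm$counts, 2L, colSums(pfm$counts), "/")
  h <- apply(p, 2L, function(col) {
    col <- col[col > 0]
    -sum(col * log2(col))
  })
  ic <- 2 - h
  if (per_column) ic else sum(ic)
}

#' Read motifs in JASPAR flat PFM format
#'
#' Parses the `>ID NAME` + four count-row format, with or without the
#' `A [ ... ]` base/bracket decorations. Rows without base letters are taken
#' in A,C,G,T order.
#'
#' @param path file path (or a character vector of lines via `text`).
#' @param text optional character vector of lines, used instead of `path`.
#' @return a named list of `pfm` objects.
#' @export
read_jaspar <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no JASPAR records found", call. = FALSE)
  ends <- c(headers[-1L] - 1L, length(lines))
  out <- list()
  for (k in seq_along(headers)) {
    block <- lines[headers[k]:ends[k]]
    hdr <- strsplit(sub("^>\\s*", "", block[1L]), "\\s+")[[1L]]
    id <- hdr[1L]
    name <- if (length(hdr) > 1L) paste(hdr[-1L], collapse = " ") else id
    rows <- block[-1L]
    if (length(rows) != 4L) {
      stop("JASPAR record ", id, " does not have 4 count rows", call. = FALSE)
    }
    base_tags <- toupper(sub("^([ACGTacgt]).*$", "\\1", rows))
    has_tags <- all(base_tags %in% DNA_BASES) && !anyDuplicated(base_tags)
    counts <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]", "", r)
      r <- gsub("[][]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    })
    widths <- lengths(counts)
    if (length(unique(widths)) != 1L) {
      stop("JASPAR record ", id, " has ragged count rows", call. = FALSE)
    }
    m <- do.call(rbind, counts)
    if (has_tags) m <- m[match(DNA_BASES, base_tags), , drop = FALSE]
    out[[id]] <- pfm(id, m, name = name)
  }
  out
}

#' Write motifs in JASPAR flat PFM format
#'
#' @param pfms a `pfm` or list of `pfm` objects.
#' @param path output file path.
#' @export
write_jaspar <- function(pfms, path) {
  if (inherits(pfms, "pfm")) pfms <- list(pfms)
  lines <- unlist(lapply(pfms, function(p) {
    c(paste0(">", p$tf_id, " ", p$name),
      vapply(1:4, function(i) {
        paste0(DNA_BASES[i], " [ ",
               paste(format(p$counts[i, ], trim = TRUE), collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
}

#' Read motifs in MEME minimal format
#'
#' Supports the minimal motif format: `MOTIF id [name]` followed by a
#' `letter-probability matrix:` line and W probability rows. Probabilities
#' are converted to counts by multiplying with `nsites` (default 100 when
#' the header omits it).
#'
#' @param path file path.
#' @return a named list of `pfm` objects.
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MEME motifs found", call. = FALSE)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(lines[s], "\\s+")[[1L]]
    id <- hdr[2L]
    name <- if (length(hdr) > 2L) hdr[3L] else id
    mat_line <- s + grep("^letter-probability matrix",
                         lines[(s + 1L):length(lines)])[1L]
    nsites <- 100
    ns <- regmatches(lines[mat_line],
                     regexpr("nsites=\\s*[0-9.]+", lines[mat_line]))
    if (length(ns)) nsites <- as.numeric(sub("nsites=\\s*", "", ns))
    w <- NA_integer_
    wm <- regmatches(lines[mat_line], regexpr("w=\\s*[0-9]+", lines[mat_line]))
    if (length(wm)) w <- as.integer(sub("w=\\s*", "", wm))
    probs <- list()
    j <- mat_line + 1L
    while (j <= length(lines) && grepl("^[0-9.eE+ -]+$", lines[j]) &&
           nzchar(lines[j])) {
      probs[[length(probs) + 1L]] <- as.numeric(strsplit(lines[j], "\\s+")[[1L]])
      j <- j + 1L
      if (!is.na(w) && length(probs) == w) break
    }
    m <- t(do.call(rbind, probs)) * nsites
    out[[id]] <- pfm(id, m, name = name)
  }
  out
}
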