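#' Labelled genomic intervals (0-based half-open)
#'
#' Chromatin-element tracks are held as plain data.frames in BED-style
#' 0-based half-open coordinates with a free-text label per interval
#' (track class, e.g. "DHS", "H3K27ac", "H3K4me1", "TF-ChIP:CEBPB",
#' "ChromHMM:strong_enhancer", "promoter").
#'
#' @param chrom,start,end,label vectors of equal length; start < end.
#' @param score optional numeric score.
#' @param strand optional strand ("+", "-", "."); chromatin tracks are
#'   unstranded and default to ".".
#' @return data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, label,
                              score = NA_real_, strand = ".") {
  d <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), label = as.character(label),
                  score = as.numeric(score), strand = as.character(strand),
                  stringsAsFactors = FALSE)
  if (nrow(d) && any(d$start >= d$end)) {
    stop("intervals must satisfy start < end (0-based half-open)",
         call. = FALSE)
  }
  if (nrow(d) && any(!nzchar(d$chrom))) {
    stop("chrom names must be nonempty", call. = FALSE)
  }
  class(d) <- c("genomic_intervals", "data.frame")
  d
}

#' Convert a printed 1-based fully-closed span to 0-based half-open
#'
#' Genome-browser style spans like "chr17:41810335-41810590" are 1-based
#' and inclusive of both ends; internally intervals are 0-based half-open.
#'
#' @param start1,end1 1-based inclusive coordinates.
#' @return list with `start` and `end` in 0-based half-open convention.
#' @export
closed1_to_halfopen0 <- function(start1, end1) {
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

#' Read / write BED (3, 4 or 6 columns)
#'
#' Coordinates are kept exactly as in the file (BED is 0-based half-open).
#' The label comes from the BED name column when present, else from
#' `default_label`.
#'
#' @param path file path.
#' @param default_label label for BED3 files (no name column).
#' @return `read_bed` returns a [genomic_intervals()] data.frame.
#' @export
read_bed <- function(path, default_label = basename(path)) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE, comment.char = "#")
  n <- ncol(d)
  genomic_intervals(chrom = d[[1]], start = d[[2]], end = d[[3]],
                    label = if (n >= 4) d[[4]] else default_label,
                    score = if (n >= 5) suppressWarnings(as.numeric(d[[5]]))
                            else NA_real_,
                    strand = if (n >= 6) d[[6]] else ".")
}

#' @rdname read_bed
#' @param x a [genomic_intervals()] data.frame.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "genomic_intervals"))
  out <- data.frame(x$chrom, x$start, x$end, x$label,
                    ifelse(is.na(x$score), 0, x$score), x$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Harmonise "chr17" vs "17" naming between two chromosome vectors.
# "auto" strips a uniform "chr" prefix from whichever side has one; raises
# when a side mixes both conventions (ambiguous).
harmonize_chroms <- function(a, b, aliasing = c("auto", "strip", "none")) {
  aliasing <- match.arg(aliasing)
  if (aliasing == "none") return(list(a = a, b = b))
  strip <- function(x) sub("^chr", "", x)
  mixed <- function(x) {
    has <- grepl("^chr", x)
    any(has) && !all(has)
  }
  if (aliasing == "auto") {
    if (mixed(a) || mixed(b)) {
      stop("ambiguous chromosome naming (mixed 'chr' prefixes); ",
           "normalise inputs or set aliasing = 'strip'", call. = FALSE)
    }
  }
  list(a = strip(a), b = strip(b))
}

#' Intersect variants with chromatin-element tracks
#'
#' A variant at 1-based position p overlaps a 0-based half-open interval
#' [s, e) iff s <= p - 1 < e. Overlapping track labels are reported in a
#' deterministic order (label, then interval start) and each variant is
#' assigned a regulatory class via [classify_regulatory()].
#'
#' @param variants data.frame with columns chrom, pos (1-based), id.
#' @param tracks a [genomic_intervals()] data.frame.
#' @param rule classification rule, see [classify_regulatory()].
#' @param chrom_aliasing how to reconcile "chr17" vs "17" naming:
#'   "auto" (strip a uniform prefix; error on mixed naming), "strip", or
#'   "none".
#' @return data.frame with one row per variant: chrom, pos, id,
#'   n_overlaps, overlapping (list-column of label vectors),
#'   regulatory_class.
#' @export
intersect_variants <- function(variants, tracks,
                               rule = default_classification_rule(),
                               chrom_aliasing = "auto") {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id")
  if (!all(need %in% names(variants))) {
    stop("`variants` must have columns chrom, pos, id", call. = FALSE)
  }
  stopifnot(inherits(tracks, "genomic_intervals"))
  h <- harmonize_chroms(variants$chrom, tracks$chrom, chrom_aliasing)
  v_gr <- GenomicRanges::GRanges(h$a,
                                 IRanges::IRanges(variants$pos, width = 1L))
  t_gr <- GenomicRanges::GRanges(h$b,
                                 IRanges::IRanges(tracks$start + 1L,
                                                  tracks$end))
  ov <- GenomicRanges::findOverlaps(v_gr, t_gr, ignore.strand = TRUE)
  hit_v <- S4Vectors::queryHits(ov)
  hit_t <- S4Vectors::subjectHits(ov)
  overlapping <- lapply(seq_len(nrow(variants)), function(i) {
    k <- hit_t[hit_v == i]
    if (!length(k)) return(character())
    k <- k[order(tracks$label[k], tracks$start[k])]
    tracks$label[k]
  })
  cls <- vapply(overlapping, classify_regulatory, character(1), rule = rule)
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    id = variants$id,
                    n_overlaps = lengths(overlapping),
                    regulatory_class = cls, stringsAsFactors = FALSE)
  out$overlapping <- overlapping
  out
}

#' Default regulatory classification rule
#'
#' The rule formalises the descriptive use of chromatin elements when
#' prioritising variants: strong enhancer evidence is either an explicit
#' ChromHMM strong-enhancer state or open chromatin (DHS) together with an
#' active/poised enhancer histone mark (H3K27ac or H3K4me1); weak evidence
#' is a ChromHMM weak-enhancer state or exactly one of the three marks.
#' A configured promoter interval downgrades unclassified variants to
#' promoter_proximal rather than none.
#'
#' @param dhs_label,h3k27ac_label,h3k4me1_label,promoter_label label strings
#'   (matched case-insensitively).
#' @param strong_state,weak_state ChromHMM labels.
#' @return a list understood by [classify_regulatory()].
#' @export
default_classification_rule <- function(dhs_label = "DHS",
                                        h3k27ac_label = "H3K27ac",
                                        h3k4me1_label = "H3K4me1",
                                        promoter_label = "promoter",
                                        strong_state = "ChromHMM:strong_enhancer",
                                        weak_state = "ChromHMM:weak_enhancer") {
  list(dhs = dhs_label, h3k27ac = h3k27ac_label, h3k4me1 = h3k4me1_label,
       promoter = promoter_label, strong_state = strong_state,
       weak_state = weak_state)
}

#' Classify a variant's regulatory context from its overlap label set
#'
#' A pure function of the set of overlapping track labels; see
#' [default_classification_rule()] for the default logic. Labels that are
#' neither one of the configured marks, a ChromHMM state, a TF-ChIP track
#' nor the promoter label are ignored with a warning.
#'
#' @param labels character vector of overlapping track labels.
#' @param rule a [default_classification_rule()] list.
#' @return one of "strong_enhancer", "weak_enhancer", "promoter_proximal",
#'   "none".
#' @export
classify_regulatory <- function(labels, rule = default_classification_rule()) {
  labels <- unique(tolower(labels))
  known_exact <- tolower(c(rule$dhs, rule$h3k27ac, rule$h3k4me1,
                           rule$promoter, rule$strong_state, rule$weak_state))
  recognised <- labels %in% known_exact |
    grepl("^chromhmm:", labels) | grepl("^tf-chip:", labels) |
    grepl("^motif:", labels)
  if (any(!recognised)) {
    warning("ignoring unknown track label(s): ",
            paste(labels[!recognised], collapse = ", "), call. = FALSE)
    labels <- labels[recognised]
  }
  has <- function(lab) tolower(lab) %in% labels
  marks <- c(has(rule$dhs), has(rule$h3k27ac), has(rule$h3k4me1))
  if (has(rule$strong_state) || (marks[1] && (marks[2] || marks[3]))) {
    return("strong_enhancer")
  }
  if (has(rule$weak_state) || sum(marks) == 1L) {
    return("weak_enhancer")
  }
  if (has(rule$promoter)) {
    return("promoter_proximal")
  }
  "none"
}

#' Write variant annotations as TSV
#'
#' The list-column of overlapping labels is flattened to a comma-separated
#' field.
#'
#' @param annotations output of [intersect_variants()].
#' @param path output path.
#' @export
write_annotations_tsv <- function(annotations, path) {
  out <- annotations
  out$overlapping <- vapply(annotations$overlapping, paste,
                            character(1), collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
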