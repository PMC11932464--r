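#' Equal-spacing analysis of motif anchor coordinates
#'
#' Enumerates maximal arithmetic progressions of length >= 3 among a set of
#' anchor coordinates (e.g. the anchor base of each motif occurrence),
#' allowing the common difference to deviate by at most `tolerance_bp`
#' between consecutive steps, and reports all pairwise gaps. A progression
#' is maximal when it cannot be extended by another anchor on either side.
#'
#' @param anchors numeric vector of 1-based coordinates, ideally sorted
#'   ascending (unsorted input is sorted with a warning).
#' @param tolerance_bp allowed per-step deviation from the common
#'   difference (default 0: exact spacing only).
#' @return object of class `spacing_result`: `anchors` (sorted),
#'   `progressions` (data.frame start_anchor, common_difference, length)
#'   and `pairwise_gaps` (all gaps a_j - a_i for i < j).
#' @export
spacing_analysis <- function(anchors, tolerance_bp = 0L) {
  anchors <- as.numeric(anchors)
  if (length(anchors) < 2L) stop("need at least 2 anchors", call. = FALSE)
  if (is.unsorted(anchors)) {
    warning("anchors were not sorted ascending; sorting", call. = FALSE)
    anchors <- sort(anchors)
  }
  anchors <- unique(anchors)
  n <- length(anchors)
  gaps <- if (n >= 2L) {
    cmb <- utils::combn(n, 2L)
    anchors[cmb[2L, ]] - anchors[cmb[1L, ]]
  } else {
    numeric(0)
  }
  tol <- as.numeric(tolerance_bp)
  progressions <- list()
  if (n >= 3L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- anchors[j] - anchors[i]
        if (d <= 0) next
        # maximal on the left: no anchor one step of size ~d before a_i
        if (any(abs((anchors[i] - anchors[seq_len(i - 1L)]) - d) <= tol)) next
        # greedy rightward extension, nearest candidate within tolerance
        members <- c(i, j)
        repeat {
          expected <- anchors[members[length(members)]] + d
          cand <- which(abs(anchors - expected) <= tol)
          cand <- cand[cand > members[length(members)]]
          if (!length(cand)) break
          nxt <- cand[which.min(abs(anchors[cand] - expected))]
          members <- c(members, nxt)
        }
        if (length(members) >= 3L) {
          progressions[[length(progressions) + 1L]] <-
            data.frame(start_anchor = anchors[i], common_difference = d,
                       length = length(members))
        }
      }
    }
  }
  progressions <- if (length(progressions)) {
    out <- unique(do.call(rbind, progressions))
    out <- out[order(out$start_anchor, out$common_difference), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(start_anchor = numeric(), common_difference = numeric(),
               length = integer())
  }
  structure(list(anchors = anchors, progressions = progressions,
                 pairwise_gaps = gaps),
            class = "spacing_result")
}

#' @export
print.spacing_result <- function(x, ...) {
  cat("<spacing_result> ", length(x$anchors), " anchors, ",
      nrow(x$progressions), " arithmetic progression(s) of length >= 3\n",
      sep = "")
  if (nrow(x$progressions)) print(x$progressions)
  invisible(x)
}

#' Write a spacing result as TSV
#'
#' @param x a [spacing_analysis()] result.
#' @param path output path.
#' @export
write_spacing_tsv <- function(x, path) {
  stopifnot(inherits(x, "spacing_result"))
  write.table(x$progressions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
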