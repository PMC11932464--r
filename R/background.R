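#' Sequence background models
#'
#' A background model describes the base composition that motif scores and
#' binding-affinity p-values are calibrated against. Order 0 is an i.i.d.
#' base distribution; order 1 is a first-order Markov chain given by a 4x4
#' transition matrix plus the marginal distribution used for the first base.
#'
#' @param base_freqs numeric length-4 vector of A/C/G/T frequencies
#'   (order-0 model). Must be positive and sum to 1.
#' @param transition 4x4 row-stochastic matrix of base-to-base transition
#'   probabilities (order-1 model), rows/cols in A,C,G,T order.
#' @param stationary length-4 marginal distribution used for the first base
#'   of an order-1 chain and as the base composition for log-odds scoring.
#' @return an object of class `background_model`.
#' @export
background_model <- function(base_freqs = NULL, transition = NULL,
                             stationary = NULL) {
  if (!is.null(base_freqs)) {
    base_freqs <- as.numeric(base_freqs)
    if (length(base_freqs) != 4L || any(base_freqs <= 0) ||
        abs(sum(base_freqs) - 1) > 1e-9) {
      stop("`base_freqs` must be 4 positive values summing to 1", call. = FALSE)
    }
    names(base_freqs) <- DNA_BASES
    return(structure(list(order = 0L, base_freqs = base_freqs),
                     class = "background_model"))
  }
  if (is.null(transition) || is.null(stationary)) {
    stop("supply `base_freqs` (order 0) or `transition` + `stationary` (order 1)",
         call. = FALSE)
  }
  transition <- as.matrix(transition)
  stationary <- as.numeric(stationary)
  if (!all(dim(transition) == c(4L, 4L)) || any(transition <= 0) ||
      any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("`transition` must be a 4x4 positive row-stochastic matrix",
         call. = FALSE)
  }
  if (length(stationary) != 4L || any(stationary <= 0) ||
      abs(sum(stationary) - 1) > 1e-9) {
    stop("`stationary` must be 4 positive values summing to 1", call. = FALSE)
  }
  dimnames(transition) <- list(DNA_BASES, DNA_BASES)
  names(stationary) <- DNA_BASES
  structure(list(order = 1L, transition = transition, stationary = stationary),
            class = "background_model")
}

#' @rdname background_model
#' @export
uniform_background <- function() background_model(base_freqs = rep(0.25, 4))

#' Promoter-like background preset
#'
#' A GC-rich order-1 chain with CpG depletion, standing in for a
#' human-promoter-like composition when no empirical background table is
#' available. Marginal composition (A,C,G,T) = (0.22, 0.28, 0.28, 0.22);
#' the C-to-G transition is halved and the row renormalised.
#'
#' @return a `background_model` of order 1.
#' @export
promoter_background <- function() {
  marginal <- c(A = 0.22, C = 0.28, G = 0.28, T = 0.22)
  tr <- matrix(rep(marginal, times = 4L), nrow = 4L, byrow = TRUE,
               dimnames = list(DNA_BASES, DNA_BASES))
  tr["C", "G"] <- tr["C", "G"] * 0.5  # CpG depletion
  tr <- tr / rowSums(tr)
  background_model(transition = tr, stationary = marginal)
}

# Marginal base frequencies of a background model (used for log-odds).
background_freqs <- function(bg) {
  stopifnot(inherits(bg, "background_model"))
  if (bg$order == 0L) bg$base_freqs else bg$stationary
}

#' Draw random sequences from a background model
#'
#' @param bg a `background_model`.
#' @param length sequence length in bp.
#' @param n number of sequences.
#' @return character vector of `n` uppercase ACGT strings.
#' @export
simulate_background_seq <- function(bg, length, n = 1L) {
  stopifnot(inherits(bg, "background_model"))
  length <- as.integer(length)
  n <- as.integer(n)
  if (length < 1L || n < 1L) stop("`length` and `n` must be >= 1", call. = FALSE)
  if (bg$order == 0L) {
    draws <- sample.int(4L, n * length, replace = TRUE, prob = bg$base_freqs)
    m <- matrix(draws, nrow = n)
  } else {
    m <- matrix(0L, nrow = n, ncol = length)
    m[, 1L] <- sample.int(4L, n, replace = TRUE, prob = bg$stationary)
    for (j in seq_len(length - 1L) + 1L) {
      prev <- m[, j - 1L]
      for (b in 1:4) {
        idx <- which(prev == b)
        if (length(idx)) {
          m[idx, j] <- sample.int(4L, base::length(idx), replace = TRUE,
                                  prob = bg$transition[b, ])
        }
      }
    }
  }
  apply(m, 1L, decode_dna)
}
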