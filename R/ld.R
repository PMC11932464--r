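#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes r^2 and D' for two sites directly from haplotype frequencies:
#' with p_a, p_b the frequencies of the "1" allele at each site and p_ab
#' the frequency of the 1-1 haplotype, D = p_ab - p_a p_b,
#' r^2 = D^2 / (p_a (1-p_a) p_b (1-p_b)), and D' = |D| / D_max with
#' D_max = min(p_a (1-p_b), (1-p_a) p_b) when D > 0 and
#' min(p_a p_b, (1-p_a)(1-p_b)) otherwise.
#'
#' @param panel a [haplotype_panel()].
#' @param i,j site indices (integers) or site ids (strings); i != j.
#' @return list of class `ld_stats` with r2, d_prime, p_a, p_b, p_ab.
#' @export
pairwise_ld <- function(panel, i, j) {
  stopifnot(inherits(panel, "haplotype_panel"))
  i <- resolve_site(panel, i)
  j <- resolve_site(panel, j)
  if (i == j) stop("`i` and `j` must be different sites", call. = FALSE)
  x <- panel$alleles[, i]
  y <- panel$alleles[, j]
  p_a <- mean(x)
  p_b <- mean(y)
  if (p_a == 0 || p_a == 1 || p_b == 0 || p_b == 1) {
    stop("undefined LD: monomorphic site (",
         panel$sites$id[if (p_a %in% c(0, 1)) i else j], ")", call. = FALSE)
  }
  p_ab <- mean(x == 1L & y == 1L)
  D <- p_ab - p_a * p_b
  r2 <- D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  d_max <- if (D > 0) {
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else {
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  }
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  structure(list(r2 = r2, d_prime = d_prime, p_a = p_a, p_b = p_b,
                 p_ab = p_ab),
            class = "ld_stats")
}

resolve_site <- function(panel, site) {
  if (is.character(site)) {
    idx <- match(site, panel$sites$id)
    if (is.na(idx)) stop("site ", sQuote(site), " not in panel", call. = FALSE)
    idx
  } else {
    idx <- as.integer(site)
    if (idx < 1L || idx > ncol(panel$alleles)) {
      stop("site index out of range", call. = FALSE)
    }
    idx
  }
}

#' Select proxy SNPs for a lead variant
#'
#' Returns every site within `window_bp` of the lead (same chromosome)
#' whose r^2 with the lead reaches `r2_threshold`, sorted by genomic
#' position. The lead itself is excluded; monomorphic candidate sites
#' cannot be proxies and are skipped.
#'
#' @param panel a [haplotype_panel()].
#' @param lead_id site id of the lead variant.
#' @param r2_threshold minimum r^2 (default 0.8, the usual proxy cut).
#' @param window_bp half-window around the lead position (default 500 kb).
#' @return object of class `proxy_set`: lead_id, threshold, and a
#'   data.frame `proxies` (id, chrom, pos, r2, d_prime).
#' @export
select_proxies <- function(panel, lead_id, r2_threshold = 0.8,
                           window_bp = 500000L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (window_bp <= 0) stop("`window_bp` must be > 0", call. = FALSE)
  lead <- resolve_site(panel, lead_id)
  lead_col <- panel$alleles[, lead]
  if (length(unique(lead_col)) == 1L) {
    stop("undefined LD: lead site is monomorphic", call. = FALSE)
  }
  lead_chrom <- panel$sites$chrom[lead]
  lead_pos <- panel$sites$pos[lead]
  cand <- which(panel$sites$chrom == lead_chrom &
                  abs(panel$sites$pos - lead_pos) <= window_bp)
  cand <- setdiff(cand, lead)
  rows <- lapply(cand, function(k) {
    col <- panel$alleles[, k]
    if (length(unique(col)) == 1L) return(NULL)
    ld <- pairwise_ld(panel, lead, k)
    if (ld$r2 >= r2_threshold) {
      data.frame(id = panel$sites$id[k], chrom = panel$sites$chrom[k],
                 pos = panel$sites$pos[k], r2 = ld$r2,
                 d_prime = ld$d_prime, stringsAsFactors = FALSE)
    } else {
      NULL
    }
  })
  proxies <- do.call(rbind, rows)
  if (is.null(proxies)) {
    proxies <- data.frame(id = character(), chrom = character(),
                          pos = integer(), r2 = numeric(),
                          d_prime = numeric(), stringsAsFactors = FALSE)
  }
  proxies <- proxies[order(proxies$pos), , drop = FALSE]
  rownames(proxies) <- NULL
  structure(list(lead_id = panel$sites$id[lead], proxies = proxies,
                 threshold = r2_threshold),
            class = "proxy_set")
}

#' @export
print.proxy_set <- function(x, ...) {
  cat("<proxy_set> lead ", x$lead_id, ": ", nrow(x$proxies),
      " proxies at r2 >= ", x$threshold, "\n", sep = "")
  if (nrow(x$proxies)) print(x$proxies)
  invisible(x)
}

#' Write a proxy set as TSV
#'
#' @param x a [select_proxies()] result.
#' @param path output path.
#' @export
write_proxies_tsv <- function(x, path) {
  stopifnot(inherits(x, "proxy_set"))
  write.table(x$proxies, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Allele frequency from genotype frequencies
#'
#' For genotype frequencies f(AA), f(Aa), f(aa) of a biallelic variant the
#' frequency of allele A is f(AA) + f(Aa)/2. Used to reproduce printed
#' population allele frequencies from printed genotype frequencies.
#'
#' @param f_AA,f_Aa,f_aa nonnegative genotype frequencies summing to 1
#'   (tolerance 1e-6).
#' @return frequency of allele A.
#' @export
#' @examples
#' allele_freq_from_genotype_freqs(0.155, 0.485, 0.360)
allele_freq_from_genotype_freqs <- function(f_AA, f_Aa, f_aa) {
  fs <- c(f_AA, f_Aa, f_aa)
  if (any(!is.finite(fs)) || any(fs < 0)) {
    stop("genotype frequencies must be nonnegative", call. = FALSE)
  }
  if (abs(sum(fs) - 1) > 1e-6) {
    stop("genotype frequencies must sum to 1 (tolerance 1e-6)", call. = FALSE)
  }
  f_AA + f_Aa / 2
}
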