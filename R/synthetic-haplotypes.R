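#' Phased haplotype panels
#'
#' A haplotype panel is a 0/1 allele matrix (rows = phased haplotypes,
#' columns = biallelic sites) plus per-site metadata. It is the input to
#' the LD computations; two haplotypes per diploid sample, so the number of
#' haplotypes must be even.
#'
#' @param alleles n_haplotypes x n_sites matrix with entries in \{0, 1\}.
#' @param sites data.frame with columns chrom, pos (1-based), ref, alt, id;
#'   one row per column of `alleles`, positions strictly increasing within
#'   each chromosome.
#' @param seed the seed the panel was generated with (NA for imported data).
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, sites, seed = NA_integer_) {
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0L, 1L))) {
    stop("allele matrix entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L) {
    stop("number of haplotypes must be even (phased diploid panel)",
         call. = FALSE)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(need %in% names(sites))) {
    stop("`sites` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sites) != ncol(alleles)) {
    stop("`sites` rows must match allele matrix columns", call. = FALSE)
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("site positions must be strictly increasing per chromosome",
           call. = FALSE)
    }
  }
  if (anyDuplicated(sites$id)) stop("site ids must be unique", call. = FALSE)
  colnames(alleles) <- sites$id
  structure(list(alleles = alleles, sites = sites, seed = seed),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", nrow(x$alleles), " haplotypes x ",
      ncol(x$alleles), " sites on ",
      paste(unique(x$sites$chrom), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Simulate a haplotype panel with block-wise LD
#'
#' Within a block every site is a copy of one founder column, giving
#' pairwise r^2 = 1; between blocks a fraction `between_block_shuffle` of
#' haplotype labels is permuted independently per block, degrading
#' cross-block LD (1.0 shuffles every haplotype, making blocks effectively
#' independent). This produces the controlled r^2 structure the proxy
#' screen consumes without a population-genetic simulation.
#'
#' @param n_haplotypes even integer >= 4.
#' @param block_sizes integer vector; number of sites per LD block.
#' @param between_block_shuffle fraction in `[0, 1]` of haplotypes whose
#'   labels are permuted per block.
#' @param maf_range length-2 vector in (0, 0.5]; each block's founder minor
#'   allele frequency is drawn uniformly from this range.
#' @param seed RNG seed; identical seed reproduces the panel bit-for-bit.
#' @param chrom chromosome name for the site metadata.
#' @param start_pos position of the first site.
#' @param spacing_bp distance between consecutive sites.
#' @return a [haplotype_panel()].
#' @export
simulate_haplotype_panel <- function(n_haplotypes, block_sizes,
                                     between_block_shuffle = 0,
                                     maf_range = c(0.05, 0.5), seed,
                                     chrom = "chr17", start_pos = 41000000L,
                                     spacing_bp = 500L) {
  n_haplotypes <- as.integer(n_haplotypes)
  if (n_haplotypes < 4L || n_haplotypes %% 2L != 0L) {
    stop("`n_haplotypes` must be an even integer >= 4", call. = FALSE)
  }
  block_sizes <- as.integer(block_sizes)
  if (!length(block_sizes) || any(block_sizes < 1L)) {
    stop("each block size must be >= 1", call. = FALSE)
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must lie within (0, 0.5]", call. = FALSE)
  }
  if (between_block_shuffle < 0 || between_block_shuffle > 1) {
    stop("`between_block_shuffle` must be in [0, 1]", call. = FALSE)
  }
  n_sites <- sum(block_sizes)
  alleles <- with_seed(seed, {
    m <- matrix(0L, nrow = n_haplotypes, ncol = n_sites)
    col0 <- 0L
    for (b in seq_along(block_sizes)) {
      maf <- runif(1, maf_range[1], maf_range[2])
      founder <- rbinom(n_haplotypes, 1L, maf)
      tries <- 0L
      while (length(unique(founder)) == 1L && tries < 1000L) {
        founder <- rbinom(n_haplotypes, 1L, maf)
        tries <- tries + 1L
      }
      block <- matrix(rep(founder, block_sizes[b]), nrow = n_haplotypes)
      if (between_block_shuffle > 0) {
        k <- round(between_block_shuffle * n_haplotypes)
        if (k >= 2L) {
          rows <- sample.int(n_haplotypes, k)
          block[rows, ] <- block[sample(rows), , drop = FALSE]
        }
      }
      m[, col0 + seq_len(block_sizes[b])] <- block
      col0 <- col0 + block_sizes[b]
    }
    m
  })
  pos <- start_pos + (seq_len(n_sites) - 1L) * spacing_bp
  refalt <- with_seed(seed + 1L, {
    ref <- sample(DNA_BASES, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                  character(1))
    list(ref = ref, alt = unname(alt))
  })
  sites <- data.frame(chrom = chrom, pos = pos, ref = refalt$ref,
                      alt = refalt$alt,
                      id = sprintf("snp_%03d", seq_len(n_sites)),
                      stringsAsFactors = FALSE)
  haplotype_panel(alleles, sites, seed = as.integer(seed))
}

#' Write / read a haplotype panel as TSV
#'
#' One row per site: the five site-metadata columns followed by one 0/1
#' column per haplotype (h1..hN).
#'
#' @param panel a [haplotype_panel()].
#' @param path file path.
#' @return `read_haplotypes_tsv` returns a [haplotype_panel()].
#' @export
write_haplotypes_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  m <- t(panel$alleles)
  colnames(m) <- paste0("h", seq_len(ncol(m)))
  out <- cbind(panel$sites, as.data.frame(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_haplotypes_tsv
#' @export
read_haplotypes_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character", ref = "character",
                                 alt = "character", id = "character"))
  hap_cols <- grep("^h[0-9]+$", names(d))
  if (!length(hap_cols)) stop("no haplotype columns (h1..hN) found", call. = FALSE)
  haplotype_panel(t(as.matrix(d[, hap_cols])),
                  d[, c("chrom", "pos", "ref", "alt", "id")])
}

#' Read a phased VCF into a haplotype panel
#'
#' Requires the vcfR package. Only biallelic SNP records with fully phased
#' GT fields ("|" separator) are accepted.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return a [haplotype_panel()].
#' @export
read_haplotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (!any(keep)) stop("no biallelic SNP records in VCF", call. = FALSE)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (any(!grepl("^[01]\\|[01]$", gt))) {
    stop("VCF genotypes must be phased biallelic (e.g. 0|1)", call. = FALSE)
  }
  h1 <- apply(gt, c(1, 2), function(g) as.integer(substr(g, 1L, 1L)))
  h2 <- apply(gt, c(1, 2), function(g) as.integer(substr(g, 3L, 3L)))
  # interleave the two haplotypes of each sample: s1.h1, s1.h2, s2.h1, ...
  n_s <- ncol(gt)
  ord <- as.vector(rbind(seq_len(n_s), seq_len(n_s) + n_s))
  alleles <- rbind(t(h1), t(h2))[ord, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"], id = ids,
                      stringsAsFactors = FALSE)
  haplotype_panel(alleles, sites)
}
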