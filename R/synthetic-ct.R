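#' Specification of a simulated qPCR Ct table
#'
#' Encodes the ground truth of a two-condition qPCR experiment: the treated
#' condition shifts the target gene's mean Ct by -log2(true_fold_change)
#' (one PCR cycle per two-fold change at efficiency 2), the reference gene
#' is unaffected by condition, and every well receives independent Gaussian
#' noise.
#'
#' @param true_fold_change programmed expression fold change (> 0).
#' @param baseline_ct_target mean target-gene Ct in the control condition.
#' @param baseline_ct_reference mean reference-gene Ct (both conditions).
#' @param noise_sd per-well Gaussian noise SD in cycles (>= 0).
#' @param n_replicates replicates per condition (>= 1).
#' @param seed RNG seed.
#' @return an object of class `ct_table_spec`.
#' @export
ct_table_spec <- function(true_fold_change, baseline_ct_target = 25,
                          baseline_ct_reference = 18, noise_sd = 0.3,
                          n_replicates = 3L, seed) {
  if (!is.numeric(true_fold_change) || true_fold_change <= 0) {
    stop("`true_fold_change` must be > 0", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  structure(list(true_fold_change = true_fold_change,
                 baseline_ct_target = baseline_ct_target,
                 baseline_ct_reference = baseline_ct_reference,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "ct_table_spec")
}

#' Simulate a qPCR Ct table with known fold change
#'
#' @param spec a [ct_table_spec()].
#' @param conditions length-2 character vector: treated label, control label.
#' @param genes length-2 character vector: target gene, reference gene.
#' @return data.frame of Ct records with columns sample_id, condition,
#'   gene, replicate, ct.
#' @export
simulate_ct_table <- function(spec, conditions = c("treated", "control"),
                              genes = c("target", "reference")) {
  stopifnot(inherits(spec, "ct_table_spec"))
  if (length(conditions) != 2L || length(genes) != 2L) {
    stop("`conditions` and `genes` must each have 2 entries", call. = FALSE)
  }
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      gene = genes, condition = conditions,
                      stringsAsFactors = FALSE)
  mean_ct <- ifelse(grid$gene == genes[1L],
                    spec$baseline_ct_target,
                    spec$baseline_ct_reference)
  treated_target <- grid$condition == conditions[1L] & grid$gene == genes[1L]
  mean_ct[treated_target] <- mean_ct[treated_target] -
    log2(spec$true_fold_change)
  noise <- with_seed(spec$seed,
                     rnorm(nrow(grid), mean = 0, sd = spec$noise_sd))
  data.frame(sample_id = paste0(grid$condition, "_r", grid$replicate),
             condition = grid$condition, gene = grid$gene,
             replicate = grid$replicate, ct = mean_ct + noise,
             stringsAsFactors = FALSE)
}
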