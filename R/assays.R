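#' Relative expression by the 2^-ddCt method
#'
#' Per condition, dCt = Ct(target) - Ct(reference); replicate-paired when
#' the two genes share the same replicate indices within the condition,
#' otherwise the condition means are used (with a note). ddCt is
#' dCt(treated) - dCt(control) and the fold change is 2^-ddCt (PCR
#' efficiency fixed at 2). The p-value is a two-sided t-test (Welch by
#' default) on the per-replicate dCt values of the two conditions; it is
#' NA when either condition lacks paired replicate dCt values.
#'
#' @param table data.frame of Ct records with columns condition, gene,
#'   replicate, ct (e.g. from [simulate_ct_table()] or
#'   [read_ct_table()]).
#' @param target_gene,reference_gene gene labels.
#' @param treated_condition,control_condition condition labels.
#' @param var_equal use the equal-variance t-test instead of Welch.
#' @return list of class `fold_change_result`: fold_change,
#'   delta_delta_ct, p_value, n_treated, n_control.
#' @export
ddct_fold_change <- function(table, target_gene, reference_gene,
                             treated_condition, control_condition,
                             var_equal = FALSE) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("condition", "gene", "replicate", "ct")
  if (!all(need %in% names(table))) {
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(table$ct)) || any(table$ct <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  cell <- function(cond, gene) {
    d <- table[table$condition == cond & table$gene == gene, , drop = FALSE]
    if (!nrow(d)) {
      stop("missing (condition, gene) cell: ", cond, " / ", gene,
           call. = FALSE)
    }
    d
  }
  dct_values <- function(cond) {
    tg <- cell(cond, target_gene)
    rf <- cell(cond, reference_gene)
    if (setequal(tg$replicate, rf$replicate) &&
        !anyDuplicated(tg$replicate) && !anyDuplicated(rf$replicate)) {
      tg$ct[order(tg$replicate)] - rf$ct[order(rf$replicate)]
    } else {
      message("replicate indices do not align for condition '", cond,
              "'; using condition means")
      mean(tg$ct) - mean(rf$ct)
    }
  }
  dct_treated <- dct_values(treated_condition)
  dct_control <- dct_values(control_condition)
  ddct <- mean(dct_treated) - mean(dct_control)
  p <- if (length(dct_treated) >= 2L && length(dct_control) >= 2L) {
    # zero-variance dCt (e.g. noiseless simulations) has no defined t-test
    tryCatch(t.test(dct_treated, dct_control, var.equal = var_equal)$p.value,
             error = function(e) NA_real_)
  } else {
    NA_real_
  }
  structure(list(fold_change = 2^(-ddct), delta_delta_ct = ddct,
                 p_value = p,
                 n_treated = nrow(cell(treated_condition, target_gene)),
                 n_control = nrow(cell(control_condition, target_gene))),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat("<fold_change_result> fold change ",
      format(x$fold_change, digits = 4),
      " (ddCt ", format(x$delta_delta_ct, digits = 4), ", p ",
      format(x$p_value, digits = 3), ", n ", x$n_treated, "/",
      x$n_control, ")\n", sep = "")
  invisible(x)
}

#' Normalise dual-luciferase reporter read-outs
#'
#' Each well's firefly signal is normalised to its renilla co-transfection
#' control; a construct's fold change is its mean firefly/renilla ratio
#' divided by the control construct's mean ratio (the control maps to 1).
#'
#' @param records data.frame with columns construct, firefly, renilla
#'   (renilla must be > 0).
#' @param control_construct label of the normalising construct.
#' @return data.frame with one row per construct: construct, n,
#'   mean_ratio, fold_change.
#' @export
reporter_normalize <- function(records, control_construct) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("construct", "firefly", "renilla")
  if (!all(need %in% names(records))) {
    stop("reporter table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(records$renilla)) || any(records$renilla <= 0)) {
    stop("renilla activity must be > 0 in every record", call. = FALSE)
  }
  if (any(records$firefly < 0)) {
    stop("firefly activity must be nonnegative", call. = FALSE)
  }
  if (!control_construct %in% records$construct) {
    stop("control construct ", sQuote(control_construct),
         " not present", call. = FALSE)
  }
  records$ratio <- records$firefly / records$renilla
  agg <- aggregate(ratio ~ construct, data = records, FUN = mean)
  n <- as.vector(table(records$construct)[agg$construct])
  ctrl <- agg$ratio[agg$construct == control_construct]
  data.frame(construct = agg$construct, n = n, mean_ratio = agg$ratio,
             fold_change = agg$ratio / ctrl, stringsAsFactors = FALSE)
}

#' Read a Ct or reporter table from TSV
#'
#' `read_ct_table` requires columns sample_id, condition, gene, replicate,
#' ct; `read_reporter_table` requires construct, firefly, renilla.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "gene", "replicate", "ct")
  if (!all(need %in% names(d))) {
    stop("Ct TSV must have header columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname read_ct_table
#' @export
read_reporter_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("construct", "firefly", "renilla")
  if (!all(need %in% names(d))) {
    stop("reporter TSV must have header columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  d
}
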