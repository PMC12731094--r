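# Relative gene-expression quantification from qPCR cycle-threshold tables
# (2^-dCt and 2^-ddCt, reference-gene normalized).

#' Validate a Ct table
#'
#' Long-format qPCR table with columns `sample`, `condition`, `gene`,
#' `replicate`, `Ct`. Ct values must be finite and non-negative; the
#' reference gene must be present for every sample.
#'
#' @param table data frame (or CSV path) in long format.
#' @param reference_gene endogenous control gene name (default `"GAPDH"`).
#' @return The validated data frame (invisibly classed `ct_table`).
#' @export
ct_table <- function(table, reference_gene = "GAPDH") {
  if (is.character(table)) table <- utils::read.csv(table,
                                                    stringsAsFactors = FALSE)
  need <- c("sample", "condition", "gene", "replicate", "Ct")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("Ct table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(table$Ct)) || any(table$Ct < 0))
    stop("Ct values must be finite and >= 0")
  for (s in unique(table$sample)) {
    genes <- table$gene[table$sample == s]
    if (!reference_gene %in% genes)
      stop("reference gene ", reference_gene, " missing for sample ", s)
  }
  class(table) <- c("ct_table", class(table))
  attr(table, "reference_gene") <- reference_gene
  table
}

#' Per-sample delta-Ct
#'
#' `dCt = mean(target Ct) - mean(reference Ct)` over replicates, per sample.
#'
#' @param table a [ct_table()] (or coercible data frame).
#' @param target_gene gene of interest.
#' @param reference_gene endogenous control (default `"GAPDH"`).
#' @return Data frame with `sample`, `condition`, `dCt` (cycles).
#' @export
delta_ct <- function(table, target_gene, reference_gene = "GAPDH") {
  if (!inherits(table, "ct_table"))
    table <- ct_table(table, reference_gene)
  out <- lapply(unique(table$sample), function(s) {
    sub <- table[table$sample == s, ]
    tg <- sub$Ct[sub$gene == target_gene]
    rf <- sub$Ct[sub$gene == reference_gene]
    if (!length(tg))
      stop("target gene ", target_gene, " missing for sample ", s)
    if (!length(rf))
      stop("reference gene ", reference_gene, " missing for sample ", s)
    data.frame(sample = s, condition = sub$condition[1],
               dCt = mean(tg) - mean(rf))
  })
  do.call(rbind, out)
}

#' Relative amount, 2^-dCt
#' @param dCt delta-Ct in cycles (finite; vectorized).
#' @return Fold amount relative to the reference gene; strictly positive
#'   and monotone decreasing in `dCt`.
#' @export
relative_amount <- function(dCt) {
  if (any(!is.finite(dCt))) stop("dCt must be finite")
  2^(-dCt)
}

#' Fold change between conditions, 2^-ddCt
#'
#' @param dCt_condition delta-Ct of the condition of interest.
#' @param dCt_control delta-Ct of the control condition.
#' @return `2^-(dCt_condition - dCt_control)`.
#' @export
ddct_fold_change <- function(dCt_condition, dCt_control) {
  if (any(!is.finite(dCt_condition)) || any(!is.finite(dCt_control)))
    stop("delta-Ct values must be finite")
  2^(-(dCt_condition - dCt_control))
}

#' Condition-level fold-change table
#'
#' For every target gene, averages per-sample delta-Ct within conditions and
#' reports the 2^-ddCt fold change of each condition against the control.
#'
#' @param table a [ct_table()] or long-format data frame / CSV path.
#' @param control_condition name of the control condition.
#' @param reference_gene endogenous control gene (default `"GAPDH"`).
#' @return Data frame with `gene`, `condition`, `dCt`, `ddCt`, `fold`.
#' @export
qpcr_fold_table <- function(table, control_condition,
                            reference_gene = "GAPDH") {
  if (!inherits(table, "ct_table")) table <- ct_table(table, reference_gene)
  if (!control_condition %in% table$condition)
    stop("control condition '", control_condition, "' not in table")
  genes <- setdiff(unique(table$gene), reference_gene)
  out <- list()
  for (g in genes) {
    d <- delta_ct(table, g, reference_gene)
    agg <- stats::aggregate(dCt ~ condition, d, mean)
    ctrl <- agg$dCt[agg$condition == control_condition]
    if (!length(ctrl))
      stop("no delta-Ct for control condition in gene ", g)
    out[[g]] <- data.frame(gene = g, condition = agg$condition,
                           dCt = agg$dCt, ddCt = agg$dCt - ctrl,
                           fold = ddct_fold_change(agg$dCt, ctrl))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
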