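# Relative gene expression by the delta-delta-CT method.

#' Validate a CT table
#'
#' A CT table is a data frame with columns `condition`, `gene`,
#' `replicate`, `ct` (threshold cycles). Replicate CT values are averaged
#' per (condition, gene) before any differencing; fold changes are
#' expressed relative to a control condition after normalisation to a
#' reference gene (GAPDH by convention).
#'
#' @param table Data frame with columns `condition`, `gene`, `replicate`,
#'   `ct`.
#' @return The table, invisibly, after validation.
#' @export
validate_ct_table <- function(table) {
  need <- c("condition", "gene", "replicate", "ct")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("CT table must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(table$ct)) || any(table$ct <= 0) || any(table$ct >= 45))
    stop("CT values must lie in (0, 45) cycles", call. = FALSE)
  invisible(table)
}

.mean_ct <- function(table, condition, gene) {
  sel <- table$condition == condition & table$gene == gene
  if (!any(sel))
    stop("CT table has no rows for condition '", condition, "', gene '",
         gene, "'", call. = FALSE)
  mean(table$ct[sel])
}

#' Reference-normalised CT difference
#'
#' `delta CT = mean CT(gene) - mean CT(reference)` within one condition,
#' with replicate CT values averaged before differencing.
#'
#' @param table A CT table (see [validate_ct_table()]).
#' @param condition Condition label.
#' @param gene Target gene label.
#' @param reference Reference gene label (default `"GAPDH"`).
#' @return Delta-CT in cycles.
#' @export
delta_ct <- function(table, condition, gene, reference = "GAPDH") {
  validate_ct_table(table)
  .mean_ct(table, condition, gene) - .mean_ct(table, condition, reference)
}

#' Relative expression fold change (delta-delta-CT)
#'
#' `fold = 2^-(dCT_treated - dCT_control)`, the conventional
#' delta-delta-CT estimate with amplification efficiency assumed exactly 2.
#'
#' @inheritParams delta_ct
#' @param treated Treated-condition label.
#' @param control Control-condition label.
#' @return Fold change (dimensionless, > 0).
#' @examples
#' tab <- data.frame(condition = rep(c("control", "VEGF"), each = 2),
#'                   gene = rep(c("GAPDH", "EGF-R"), 2),
#'                   replicate = 1L,
#'                   ct = c(18, 25, 18, 25 - 4.24))
#' fold_change(tab, "VEGF", "control", "EGF-R")  # ~18.9
#' @export
fold_change <- function(table, treated, control, gene, reference = "GAPDH") {
  ddct <- delta_ct(table, treated, gene, reference) -
    delta_ct(table, control, gene, reference)
  2^(-ddct)
}

#' Fold-change matrix over stimuli and receptor genes
#'
#' Computes [fold_change()] for every (stimulus, receptor) pair against
#' the control condition, arranged stimuli x receptors -- the layout of a
#' receptor-panel expression table.
#'
#' @inheritParams delta_ct
#' @param stimuli Character vector of treated-condition labels.
#' @param receptors Character vector of target gene labels.
#' @param control Control-condition label (default `"control"`).
#' @return Data frame of class `expression_table`: one row per stimulus,
#'   one column per receptor, fold changes relative to control.
#' @export
expression_matrix <- function(table, stimuli, receptors,
                              control = "control", reference = "GAPDH") {
  validate_ct_table(table)
  missing <- character(0)
  for (s in c(stimuli, control)) for (g in c(receptors, reference)) {
    if (!any(table$condition == s & table$gene == g))
      missing <- c(missing, paste0("(", s, ", ", g, ")"))
  }
  if (length(missing))
    stop("CT table is missing combinations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- sapply(receptors, function(g)
    vapply(stimuli, function(s)
      fold_change(table, s, control, g, reference), 1))
  out <- as.data.frame(matrix(out, nrow = length(stimuli),
                              dimnames = list(stimuli, receptors)))
  class(out) <- c("expression_table", "data.frame")
  out
}
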