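#' Two-group differential expression by Welch's t-test
#'
#' Per-gene Welch t on log2 values with two-sided p-values. The log2 fold
#' change is `mean(group2) - mean(group1)`; by convention group1 is the
#' control/reference arm (normoxia, sgNC) and group2 the treatment arm
#' (hypoxia, knockdown), so positive log2FC means induction under treatment.
#' Mean intensity is the grand mean over both groups. Genes with zero
#' variance in both groups and equal means get p = 1 by convention and are
#' flagged.
#'
#' This deliberately simple test stands behind the screen wherever only
#' thresholded DEG sets are consumed downstream; the DE backend is a module
#' boundary and can be swapped.
#'
#' @param expr Log2 expression matrix (genes x samples).
#' @param group1_ids,group2_ids Column ids of the two groups (>= 2 each).
#' @return data.frame (class `de_table`): `gene`, `mean_intensity`,
#'   `log2_fc`, `t`, `df`, `p_value`, `adj_p` (BH), `flag_degenerate`.
#' @export
two_group_de <- function(expr, group1_ids, group2_ids) {
  stopifnot(is.matrix(expr))
  miss <- setdiff(c(group1_ids, group2_ids), colnames(expr))
  if (length(miss) > 0L)
    stop("sample id(s) not in matrix: ", paste(miss, collapse = ", "))
  if (length(group1_ids) < 2L || length(group2_ids) < 2L)
    stop("need >= 2 samples per group")
  if (length(intersect(group1_ids, group2_ids)) > 0L)
    stop("groups overlap")
  x1 <- expr[, group1_ids, drop = FALSE]
  x2 <- expr[, group2_ids, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m2 - m1
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, ifelse(lfc == 0, 0, Inf * sign(lfc)),
                  lfc / sqrt(se2))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(degenerate, ifelse(lfc == 0, 1, 0),
              2 * stats::pt(-abs(tstat), df = df))
  p <- pmin(p, 1)
  if (any(degenerate))
    message("two_group_de: ", sum(degenerate),
            " gene(s) with zero variance in both groups (flagged)")
  out <- data.frame(gene = rownames(expr),
                    mean_intensity = rowMeans(expr[, c(group1_ids, group2_ids), drop = FALSE]),
                    log2_fc = lfc, t = tstat, df = df, p_value = p,
                    adj_p = bh_adjust(p), flag_degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment (monotone in rank, capped at 1), delegating to
#' `stats::p.adjust(method = "BH")` after validating the input range.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold-based DEG selection from a DE table
#'
#' Selects genes passing ALL of: mean log2 intensity strictly above
#' `min_intensity`, absolute log2 fold change strictly above `min_abs_lfc`,
#' and p-value (raw or BH-adjusted, per `p_type`) strictly below `max_p`.
#' Whether the p criterion uses raw or adjusted values is an explicit field,
#' never inferred: the xenograft-style contrast uses `p_type = "adj"`, the
#' LEC knockdown contrast uses `p_type = "raw"` as printed.
#'
#' @param det A `de_table` from [two_group_de()].
#' @param min_intensity Minimum mean log2 intensity (strict >; default 6).
#' @param min_abs_lfc Minimum |log2FC| (strict >; default 0.5).
#' @param max_p Maximum p (strict <; default 0.05).
#' @param p_type `"adj"` (BH-adjusted, default) or `"raw"`.
#' @return list (class `deg_selection`): `genes` (character), `n_up`,
#'   `n_down`, `thresholds`, `table` (selected rows).
#' @export
select_degs <- function(det, min_intensity = 6, min_abs_lfc = 0.5,
                        max_p = 0.05, p_type = c("adj", "raw")) {
  p_type <- match.arg(p_type)
  stopifnot(inherits(det, "de_table") || is.data.frame(det))
  pcol <- if (p_type == "adj") det$adj_p else det$p_value
  pass <- det$mean_intensity > min_intensity &
    abs(det$log2_fc) > min_abs_lfc &
    !is.na(pcol) & pcol < max_p
  pass[is.na(pass)] <- FALSE
  sel <- det[pass, , drop = FALSE]
  structure(list(genes = sel$gene,
                 n_up = sum(sel$log2_fc > 0),
                 n_down = sum(sel$log2_fc < 0),
                 thresholds = list(min_intensity = min_intensity,
                                   min_abs_lfc = min_abs_lfc,
                                   max_p = max_p, p_type = p_type),
                 table = sel),
            class = "deg_selection")
}

#' @export
print.deg_selection <- function(x, ...) {
  cat("deg_selection:", length(x$genes), "genes (", x$n_up, "up,", x$n_down,
      "down ) at |log2FC| >", x$thresholds$min_abs_lfc,
      ", intensity >", x$thresholds$min_intensity, ",",
      x$thresholds$p_type, "p <", x$thresholds$max_p, "\n")
  invisible(x)
}
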