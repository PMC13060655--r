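#' Per-tumor fold changes of signature genes over the healthy baseline
#'
#' Fold changes are ratios of linear-scale intensities: the log2 matrix is
#' back-transformed with `2^x`, the baseline for each gene is the arithmetic
#' mean of its linear values over the healthy samples, and each tumor value is
#' divided by that baseline.
#'
#' @param cohort An `lnc_cohort` (see [align_cohort()]).
#' @param signature A [gene_signature()], typically the 27-gene hypoxia
#'   metagene.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present in the expression matrix (default 0.8); below it an error names
#'   the missing genes.
#' @return An object of class `fold_change_table`: list with `fc` (matrix,
#'   signature genes x tumor samples, linear-scale fold changes), `baseline`
#'   (named vector of linear healthy means), `genes_used`, `genes_missing`,
#'   `signature`.
#' @export
compute_fold_changes <- function(cohort, signature, min_coverage = 0.8) {
  stopifnot(inherits(cohort, "lnc_cohort"), inherits(signature, "gene_signature"))
  present <- intersect(signature$genes, rownames(cohort$expr))
  missing <- setdiff(signature$genes, present)
  coverage <- length(present) / signature$expected_size
  if (coverage < min_coverage)
    stop(sprintf("signature coverage %.2f below min_coverage %.2f; missing genes: %s",
                 coverage, min_coverage, paste(missing, collapse = ", ")))
  if (length(missing) > 0L)
    message("compute_fold_changes: ", length(missing),
            " signature gene(s) absent from matrix: ",
            paste(missing, collapse = ", "))
  lin <- 2^cohort$expr[present, , drop = FALSE]
  baseline <- rowMeans(lin[, cohort$healthy_ids, drop = FALSE])
  fc <- lin[, cohort$tumor_ids, drop = FALSE] / baseline
  structure(list(fc = fc, baseline = baseline, genes_used = present,
                 genes_missing = missing, signature = signature),
            class = "fold_change_table")
}

#' Hypoxia metagene count score and Low/High classification
#'
#' The score of a tumor is the number of signature genes whose fold change
#' over the mean healthy expression exceeds 2 (strict inequality). With the
#' full 27-gene metagene, scores 0-14 classify the tumor `Low` and 15-27
#' `High`. When fewer genes are available (platform gaps tolerated by
#' `min_coverage` in [compute_fold_changes()]) the High threshold is rescaled
#' proportionally to `ceiling(high_threshold * G / expected_size)` and the
#' rescaling is reported via a message.
#'
#' @param fct A `fold_change_table` from [compute_fold_changes()].
#' @param high_threshold Minimum score classified High with the full
#'   signature (default 15).
#' @param fc_cutoff Fold-change cutoff (default 2; strict `>`).
#' @return data.frame with columns `sample`, `score`, `class` (factor
#'   Low/High); attributes `n_genes_used`, `high_threshold` (possibly
#'   rescaled).
#' @export
hypoxia_score <- function(fct, high_threshold = 15, fc_cutoff = 2) {
  stopifnot(inherits(fct, "fold_change_table"))
  if (nrow(fct$fc) == 0L || ncol(fct$fc) == 0L)
    stop("fold-change table is empty")
  g <- length(fct$genes_used)
  expected <- fct$signature$expected_size
  thr <- high_threshold
  if (g != expected) {
    thr <- ceiling(high_threshold * g / expected)
    message(sprintf("hypoxia_score: %d of %d signature genes available; High threshold rescaled %d -> %d",
                    g, expected, high_threshold, thr))
  }
  score <- colSums(fct$fc > fc_cutoff)
  cls <- factor(ifelse(score >= thr, "High", "Low"), levels = c("Low", "High"))
  out <- data.frame(sample = colnames(fct$fc), score = as.integer(score),
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_genes_used") <- g
  attr(out, "high_threshold") <- thr
  out
}

#' Spearman rank correlation with a mid-rank t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks; the two-sided p-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Zero variance in either vector leaves rho undefined (`NA`, flagged), never
#' silently 0.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return list with `rho`, `p_value`, `n`, `undefined` (logical flag).
#' @export
spearman_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("spearman_test needs >= 4 paired observations, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  p <- spearman_p(rho, n)
  list(rho = rho, p_value = p, n = n, undefined = FALSE)
}

#' @keywords internal
spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
  pmin(p, 1)
}

#' Association of one transcript with the hypoxia score
#'
#' Spearman rank correlation (mid-ranks, t-approximation) between a
#' transcript's expression and the integer hypoxia score across tumor
#' samples. The adjusted p-value is filled by [bh_adjust()] when many
#' transcripts are screened together (see [hypoxia_association_screen()]);
#' for a single transcript it equals the raw p.
#'
#' @param cohort An `lnc_cohort`.
#' @param transcript Gene/transcript identifier present in the matrix.
#' @param scores Score table from [hypoxia_score()].
#' @return data.frame row: `transcript`, `rho`, `p_value`, `adj_p`, `n`.
#' @export
hypoxia_association <- function(cohort, transcript, scores) {
  if (!transcript %in% rownames(cohort$expr))
    stop("transcript not in expression matrix: ", transcript)
  common <- intersect(cohort$tumor_ids, scores$sample)
  if (length(common) < 4L)
    stop("need >= 4 tumor samples with both expression and score")
  x <- cohort$expr[transcript, common]
  s <- scores$score[match(common, scores$sample)]
  st <- spearman_test(x, s)
  data.frame(transcript = transcript, rho = st$rho, p_value = st$p_value,
             adj_p = st$p_value, n = st$n, stringsAsFactors = FALSE)
}

#' Hypoxia-score association screen over many transcripts
#'
#' Vectorized Spearman association of each transcript with the hypoxia score
#' over tumor samples, BH-adjusted across the screened set. Transcripts with
#' zero expression variance get `NA` rho/p and are excluded from the
#' adjustment denominator.
#'
#' @param cohort An `lnc_cohort`.
#' @param transcripts Character vector of transcripts to screen (must be rows
#'   of the matrix; absent ones are an error).
#' @param scores Score table from [hypoxia_score()].
#' @return data.frame: `transcript`, `rho`, `p_value`, `adj_p`, `n`.
#' @export
hypoxia_association_screen <- function(cohort, transcripts, scores) {
  absent <- setdiff(transcripts, rownames(cohort$expr))
  if (length(absent) > 0L)
    stop("transcript(s) not in expression matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  common <- intersect(cohort$tumor_ids, scores$sample)
  if (length(common) < 4L)
    stop("need >= 4 tumor samples with both expression and score")
  n <- length(common)
  xm <- cohort$expr[transcripts, common, drop = FALSE]
  s_rank <- rank(scores$score[match(common, scores$sample)])
  rx <- t(apply(xm, 1L, rank))
  sds <- apply(xm, 1L, stats::sd)
  rho <- suppressWarnings(as.vector(stats::cor(t(rx), s_rank)))
  rho[sds == 0 | stats::sd(s_rank) == 0] <- NA_real_
  p <- ifelse(is.na(rho), NA_real_, spearman_p(rho, n))
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) adj[ok] <- bh_adjust(p[ok])
  data.frame(transcript = transcripts, rho = rho, p_value = p, adj_p = adj,
             n = n, stringsAsFactors = FALSE, row.names = NULL)
}
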