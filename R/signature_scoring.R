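#' Cumulative z-score of a gene signature per sample
#'
#' For each signature gene g, the z term of sample s is
#' `(x_gs - mean_g) / sd_g`, with mean and sd computed over the reference
#' samples (default: all cohort samples; the healthy-only alternative is
#' exposed through `reference_samples`). The sample score is the sum of z
#' terms over signature genes present in the matrix. sd uses the unbiased
#' (n - 1) estimator; genes with zero sd over the reference set are dropped
#' with a warning.
#'
#' @param cohort An `lnc_cohort`, or a plain log2 expression matrix.
#' @param signature A [gene_signature()] (e.g. the 141-gene stroma or immune
#'   lists).
#' @param reference_samples Sample ids over which per-gene mean/sd are
#'   computed; default all samples of the matrix. Needs >= 3 samples.
#' @return data.frame `sample`, `score`; attribute `n_genes_used`.
#' @export
zscore_signature_score <- function(cohort, signature, reference_samples = NULL) {
  expr <- if (inherits(cohort, "lnc_cohort")) cohort$expr else cohort
  stopifnot(is.matrix(expr), inherits(signature, "gene_signature"))
  if (is.null(reference_samples)) reference_samples <- colnames(expr)
  missing_ref <- setdiff(reference_samples, colnames(expr))
  if (length(missing_ref) > 0L)
    stop("reference sample(s) not in matrix: ", paste(missing_ref, collapse = ", "))
  if (length(reference_samples) < 3L)
    stop("need >= 3 reference samples to estimate per-gene mean/sd")
  genes <- intersect(signature$genes, rownames(expr))
  if (length(genes) == 0L)
    stop("no genes of signature '", signature$name, "' found in the matrix")
  sub <- expr[genes, , drop = FALSE]
  ref <- sub[, reference_samples, drop = FALSE]
  mu <- rowMeans(ref)
  sd_g <- apply(ref, 1L, stats::sd)
  drop <- sd_g == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " signature gene(s) with zero sd over the reference set: ",
            paste(utils::head(genes[drop], 5L), collapse = ", "))
    sub <- sub[!drop, , drop = FALSE]; mu <- mu[!drop]; sd_g <- sd_g[!drop]
  }
  if (nrow(sub) == 0L)
    stop("all signature genes dropped (zero sd); cannot score '", signature$name, "'")
  z <- (sub - mu) / sd_g
  out <- data.frame(sample = colnames(expr), score = colSums(z),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_genes_used") <- nrow(sub)
  attr(out, "signature") <- signature$name
  out
}

#' Pearson product-moment correlation test
#'
#' r by the product-moment formula; two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. Zero
#' variance leaves the result undefined (`NA`, flagged).
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return list `r`, `p_value`, `n`, `undefined`.
#' @export
pearson_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("pearson_test needs >= 4 paired observations, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else
    2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  list(r = r, p_value = min(p, 1), n = n, undefined = FALSE)
}
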