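#' Construct a single-cell count container
#'
#' Counts are stored genes x cells (sparse `dgCMatrix`); per-cell
#' annotations carry at minimum a cluster label, optionally donor and tissue.
#' QC metrics (detected features, percent mitochondrial counts) are computed
#' on construction from configurable id prefixes.
#'
#' @param counts Non-negative integer matrix or sparse Matrix, genes in rows
#'   (rownames required), cells in columns (colnames = barcodes).
#' @param annotations data.frame with column `barcode` (matching colnames)
#'   and `cluster`; optional `donor`, `tissue`.
#' @param mito_prefix Gene-id prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return Object of class `sc_matrix`: list `counts`, `cells`
#'   (annotations + `n_features` + `pct_mito`), `mito_prefix`.
#' @export
sc_matrix <- function(counts, annotations, mito_prefix = "MT-") {
  counts <- if (inherits(counts, "Matrix"))
    methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  else
    methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell barcodes as colnames")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers")
  if (!all(c("barcode", "cluster") %in% colnames(annotations)))
    stop("annotations need columns 'barcode' and 'cluster'")
  if (!setequal(annotations$barcode, colnames(counts)))
    stop("annotations must cover exactly the cells in the count matrix")
  cells <- annotations[match(colnames(counts), annotations$barcode), , drop = FALSE]
  mito <- startsWith(rownames(counts), mito_prefix)
  cells$n_features <- Matrix::colSums(counts > 0)
  tot <- Matrix::colSums(counts)
  cells$pct_mito <- ifelse(tot > 0, 100 * Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
  rownames(cells) <- NULL
  structure(list(counts = counts, cells = cells, mito_prefix = mito_prefix),
            class = "sc_matrix")
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat("sc_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells,",
      length(unique(x$cells$cluster)), "clusters\n")
  invisible(x)
}

#' Read a MatrixMarket single-cell triplet (MTX + features + barcodes)
#'
#' @param mtx_path MatrixMarket counts file (genes x cells).
#' @param features_path One gene id per line (or first TSV column).
#' @param barcodes_path One barcode per line.
#' @param annotations_path TSV with columns `barcode`, `cluster` and optional
#'   `donor`, `tissue`.
#' @param mito_prefix Passed to [sc_matrix()].
#' @return An `sc_matrix`.
#' @export
read_sc_mtx <- function(mtx_path, features_path, barcodes_path,
                        annotations_path, mito_prefix = "MT-") {
  counts <- Matrix::readMM(mtx_path)
  feats <- utils::read.table(features_path, sep = "\t", stringsAsFactors = FALSE)[[1L]]
  bcs <- utils::read.table(barcodes_path, sep = "\t", stringsAsFactors = FALSE)[[1L]]
  if (nrow(counts) != length(feats) || ncol(counts) != length(bcs))
    stop("MTX dimensions do not match features/barcodes files")
  dimnames(counts) <- list(feats, bcs)
  ann <- utils::read.table(annotations_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  sc_matrix(counts, ann, mito_prefix = mito_prefix)
}

#' Read a dense TSV single-cell count matrix
#'
#' Fallback for small matrices: genes in rows (first column = gene id),
#' barcodes in the header.
#'
#' @inheritParams read_sc_mtx
#' @param counts_path Dense TSV path.
#' @return An `sc_matrix`.
#' @export
read_sc_dense <- function(counts_path, annotations_path, mito_prefix = "MT-") {
  mat <- read_expression_matrix(counts_path, scale = "log2")  # parsed as-is
  ann <- utils::read.table(annotations_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  sc_matrix(mat, ann, mito_prefix = mito_prefix)
}

#' Quality-control filtering of a single-cell matrix
#'
#' Applies the standard droplet QC rules: remove ribosomal genes (by id
#' prefix), genes detected in fewer than `min_cells` cells, cells with fewer
#' than `min_features` detected genes (low-quality), more than `max_features`
#' detected genes (possible doublets) or more than `max_pct_mito` percent
#' mitochondrial counts (apoptotic/lysed). All boundaries follow the quoted
#' rules strictly: a cell with exactly 5% mitochondrial counts or exactly
#' 7500 features is retained; one with exactly 200 features is retained
#' ("fewer than 200" removed).
#'
#' Removal is iterated to a fixed point so the operation is idempotent
#' (dropping cells can push a gene below `min_cells` and vice versa); the
#' per-rule counts reported come from the first pass.
#'
#' @param sc An `sc_matrix`.
#' @param min_cells Gene floor: detected in >= 3 cells (removed if fewer).
#' @param min_features Cell floor: removed if fewer than 200 detected genes.
#' @param max_features Cell ceiling: removed if more than 7500 detected genes.
#' @param max_pct_mito Removed if strictly more than 5 percent mitochondrial.
#' @param ribo_prefixes Gene-id prefixes removed outright (default
#'   `c("RPL", "RPS")`).
#' @return Filtered `sc_matrix`; attribute `qc_report` (list of per-rule
#'   removal counts and removed barcodes per rule).
#' @export
qc_filter <- function(sc, min_cells = 3, min_features = 200,
                      max_features = 7500, max_pct_mito = 5,
                      ribo_prefixes = c("RPL", "RPS")) {
  stopifnot(inherits(sc, "sc_matrix"))
  counts <- sc$counts
  report <- NULL
  repeat {
    det <- Matrix::colSums(counts > 0)
    tot <- Matrix::colSums(counts)
    mito <- startsWith(rownames(counts), sc$mito_prefix)
    pct_mito <- ifelse(tot > 0, 100 * Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
    low <- det < min_features
    high <- det > max_features
    mito_bad <- pct_mito > max_pct_mito
    ribo <- Reduce(`|`, lapply(ribo_prefixes,
                               function(p) startsWith(rownames(counts), p)))
    rare <- Matrix::rowSums(counts > 0) < min_cells
    if (is.null(report)) {
      report <- list(
        cells_low_features = sum(low), cells_high_features = sum(high),
        cells_high_mito = sum(mito_bad),
        genes_ribosomal = sum(ribo), genes_rare = sum(rare & !ribo),
        removed_low_features = colnames(counts)[low],
        removed_high_features = colnames(counts)[high],
        removed_high_mito = colnames(counts)[mito_bad])
    }
    drop_cells <- low | high | mito_bad
    drop_genes <- ribo | rare
    if (!any(drop_cells) && !any(drop_genes)) break
    counts <- counts[!drop_genes, !drop_cells, drop = FALSE]
    if (ncol(counts) == 0L) stop("qc_filter removed all cells")
    if (nrow(counts) == 0L) stop("qc_filter removed all genes")
  }
  ann_cols <- setdiff(colnames(sc$cells), c("n_features", "pct_mito"))
  out <- sc_matrix(counts,
                   sc$cells[sc$cells$barcode %in% colnames(counts), ann_cols,
                            drop = FALSE],
                   mito_prefix = sc$mito_prefix)
  attr(out, "qc_report") <- report
  out
}

#' Library-size normalization with log transform
#'
#' Scales each cell's counts to a common library size (default 10,000) and
#' applies `log1p`, the standard dialect of per-cell normalization for
#' droplet data.
#'
#' @param sc An `sc_matrix` (post-QC; a zero-count cell is an error).
#' @param scale_factor Target library size (default 1e4).
#' @param log Apply `log1p` after scaling (default TRUE). `log = FALSE`
#'   returns linear normalized counts, the scale on which cluster-mean fold
#'   ratios keep their "times more expressed" meaning (the field's dot-plot
#'   average-expression convention).
#' @return Sparse genes x cells matrix of normalized values.
#' @export
normalize_log <- function(sc, scale_factor = 1e4, log = TRUE) {
  stopifnot(inherits(sc, "sc_matrix"))
  lib <- Matrix::colSums(sc$counts)
  if (any(lib == 0))
    stop("zero-count cell(s) present; run qc_filter first: ",
         paste(utils::head(colnames(sc$counts)[lib == 0], 5L), collapse = ", "))
  norm <- sc$counts %*% Matrix::Diagonal(x = scale_factor / lib)
  colnames(norm) <- colnames(sc$counts)
  rownames(norm) <- rownames(sc$counts)
  if (log) norm@x <- log1p(norm@x)
  norm
}

#' End-to-end restriction analysis of one transcript
#'
#' Convenience wrapper: QC-filters the matrix, normalizes, summarizes the
#' query and marker genes per cluster on the linear normalized scale (so the
#' fold gate compares expression ratios) and computes the restriction score.
#'
#' @param sc An `sc_matrix` (raw counts).
#' @param gene Query transcript.
#' @param markers Character vector of marker genes for concordance profiles.
#' @param min_fold Fold gate passed to [restriction_score()].
#' @param qc Run [qc_filter()] first (default TRUE).
#' @return list `score` (a `restriction_score`), `summary`
#'   (`cluster_summary` of the query), `marker_summaries`, `qc_report`.
#' @export
restrict_transcript <- function(sc, gene, markers = character(0),
                                min_fold = 10, qc = TRUE) {
  if (qc) sc <- qc_filter(sc)
  norm <- normalize_log(sc, log = FALSE)
  labels <- sc$cells$cluster
  qs <- cluster_summary(norm, labels, gene)
  ms <- NULL
  if (length(markers) > 0L) {
    ms <- lapply(markers, function(m) cluster_summary(norm, labels, m))
    names(ms) <- markers
  }
  list(score = restriction_score(qs, ms, min_fold = min_fold),
       summary = qs, marker_summaries = ms,
       qc_report = attr(sc, "qc_report"))
}

#' Per-cluster expression summary for one gene
#'
#' @param norm Normalized genes x cells matrix (see [normalize_log()]).
#' @param labels Cluster label per cell (same order/length as columns).
#' @param gene Gene identifier (error naming it when absent).
#' @return data.frame (class `cluster_summary`): `cluster`, `mean_expr`,
#'   `detection_fraction` (cells with value > 0), `n_cells`; attribute
#'   `gene`.
#' @export
cluster_summary <- function(norm, labels, gene) {
  if (!gene %in% rownames(norm))
    stop("gene not found in matrix: ", gene)
  if (length(labels) != ncol(norm))
    stop("labels must cover all ", ncol(norm), " cells")
  labels <- factor(labels)
  v <- norm[gene, ]
  out <- data.frame(
    cluster = levels(labels),
    mean_expr = as.vector(tapply(v, labels, mean)),
    detection_fraction = as.vector(tapply(v > 0, labels, mean)),
    n_cells = as.vector(table(labels)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "gene") <- gene
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' Cell-type restriction score of a transcript
#'
#' Quantifies confinement of a transcript to its top cluster:
#' `score = max(cluster means) / sum(cluster means)` (1 = fully confined,
#' 1/k = uniform over k clusters), plus the fold of the top cluster mean over
#' the next-best cluster. A transcript is reported restricted when
#' `score > 0.5` AND `fold_next >= min_fold` (default 10, the magnitude
#' observed for LEC-confined transcripts). Marker concordance is the Pearson
#' correlation of the transcript's cluster-mean profile with each marker's
#' profile.
#'
#' @param summary `cluster_summary` of the query transcript.
#' @param marker_summaries Named list of `cluster_summary` objects for marker
#'   genes (e.g. PROX1, PDPN, CDH5 profiles), or NULL.
#' @param min_fold Fold-over-next-best gate (default 10).
#' @return list (class `restriction_score`): `gene`, `top_cluster`, `score`,
#'   `fold_next`, `restricted`, `concordance` (named numeric), `undefined`.
#' @export
restriction_score <- function(summary, marker_summaries = NULL, min_fold = 10) {
  stopifnot(inherits(summary, "cluster_summary"))
  if (nrow(summary) < 2L) stop("restriction score needs >= 2 clusters")
  m <- summary$mean_expr
  if (all(m == 0)) {
    return(structure(list(gene = attr(summary, "gene"), top_cluster = NA_character_,
                          score = NA_real_, fold_next = NA_real_,
                          restricted = NA, concordance = NULL, undefined = TRUE),
                     class = "restriction_score"))
  }
  top <- which.max(m)
  next_best <- max(m[-top])
  fold <- if (next_best == 0) Inf else m[top] / next_best
  score <- m[top] / sum(m)
  conc <- NULL
  if (!is.null(marker_summaries)) {
    conc <- vapply(marker_summaries, function(ms) {
      stopifnot(identical(ms$cluster, summary$cluster))
      if (stats::sd(ms$mean_expr) == 0 || stats::sd(m) == 0) return(NA_real_)
      stats::cor(m, ms$mean_expr)
    }, numeric(1L))
  }
  structure(list(gene = attr(summary, "gene"),
                 top_cluster = summary$cluster[top],
                 score = score, fold_next = fold,
                 restricted = score > 0.5 && fold >= min_fold,
                 concordance = conc, undefined = FALSE),
            class = "restriction_score")
}

#' @export
print.restriction_score <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("restriction_score: undefined (all-zero profile) for", x$gene, "\n")
    return(invisible(x))
  }
  cat(sprintf("restriction_score: %s top=%s score=%.3f fold=%.1f restricted=%s\n",
              x$gene, x$top_cluster, x$score, x$fold_next, x$restricted))
  if (!is.null(x$concordance))
    cat("  marker concordance:",
        paste(sprintf("%s r=%.2f", names(x$concordance), x$concordance),
              collapse = ", "), "\n")
  invisible(x)
}
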