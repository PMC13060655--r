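#' Read a genes-by-samples expression matrix from delimited text
#'
#' Parses a TSV/CSV expression matrix whose first column holds gene
#' identifiers and whose header row holds sample identifiers. All downstream
#' stages work on the log2 scale; a matrix tagged `linear` is transformed to
#' `log2(x + 1)` at load so that fold-change rules (which are ratios of
#' linear intensities) stay well defined.
#'
#' Duplicate gene rows are collapsed by their mean (with a warning listing
#' the identifiers). Duplicate sample columns are an error.
#'
#' @param path Path to a delimited text file. The delimiter is taken from the
#'   file extension (`.csv` = comma, anything else = tab) unless `sep` is
#'   given.
#' @param scale Either `"log2"` (values are already log2 intensities, the
#'   default) or `"linear"` (values are transformed with `log2(x + 1)`).
#' @param sep Optional field separator overriding the extension heuristic.
#' @return A numeric matrix (genes in rows, samples in columns) on log2
#'   scale, with unique row and column names.
#' @export
read_expression_matrix <- function(path, scale = c("log2", "linear"), sep = NULL) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("expression matrix file not found: ", path)
  if (file.size(path) == 0L) stop("expression matrix file is empty: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("expression matrix must have >= 1 gene row and >= 1 sample column: ", path)
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf("non-numeric or non-finite expression value at gene '%s', sample '%s' (was '%s')",
                 genes[i], samples[j], vals[i, j]))
  }
  dimnames(num) <- list(genes, samples)
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dups), " duplicated gene row(s) by mean: ",
            paste(utils::head(dups, 5L), collapse = ", "),
            if (length(dups) > 5L) ", ..." else "")
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    rownames(num) <- unique(genes)
  }
  if (scale == "linear") num <- log2(num + 1)
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] up to floating-point formatting
#' (round trips agree to well under 1e-9).
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path; the first column is named `gene`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Expects a TSV with fixed column names: `sample`, `tissue`
#' (healthy/tumor), `os_time` (days), `os_event` (0 censored / 1 death),
#' `recurrence` (no/yes, may be missing) and `stage` (I-IV, may be missing).
#' `os_time`/`os_event` may be missing for individual samples; such samples
#' are excluded from survival stages only (callers log the count).
#'
#' @param path Path to the clinical TSV.
#' @return A data.frame with validated, typed columns.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", ""))
  validate_clinical(df)
}

#' @keywords internal
validate_clinical <- function(df) {
  required <- c("sample", "tissue", "os_time", "os_event", "recurrence", "stage")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0L)
    stop("clinical table missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, required]
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample))
    stop("duplicate sample identifiers in clinical table: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (!all(df$tissue %in% c("healthy", "tumor")))
    stop("tissue must be 'healthy' or 'tumor'; offending values: ",
         paste(unique(setdiff(df$tissue, c("healthy", "tumor"))), collapse = ", "))
  df$os_time <- as.numeric(df$os_time)
  df$os_event <- as.integer(df$os_event)
  has_surv <- !is.na(df$os_time) & !is.na(df$os_event)
  if (any(df$os_time[has_surv] < 0))
    stop("os_time must be >= 0")
  if (!all(df$os_event[has_surv] %in% c(0L, 1L)))
    stop("os_event must be 0 (censored) or 1 (death)")
  ok_rec <- is.na(df$recurrence) | df$recurrence %in% c("no", "yes")
  if (!all(ok_rec)) stop("recurrence must be 'no', 'yes' or missing")
  ok_stage <- is.na(df$stage) | df$stage %in% c("I", "II", "III", "IV")
  if (!all(ok_stage)) stop("stage must be I, II, III, IV or missing")
  df
}

#' Write a clinical table as TSV
#' @param clinical Clinical data.frame as returned by [read_clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Align an expression matrix with a clinical table into a cohort
#'
#' Restricts both inputs to their common samples and splits sample ids into
#' healthy and tumor sets. Samples present in only one input are dropped with
#' a message. Idempotent: aligning a cohort's own components returns the same
#' cohort.
#'
#' @param expr Numeric log2 expression matrix (genes x samples).
#' @param clinical Clinical data.frame (see [read_clinical_table()]).
#' @return An object of class `lnc_cohort`: a list with elements `expr`,
#'   `clinical`, `healthy_ids`, `tumor_ids`.
#' @export
align_cohort <- function(expr, clinical) {
  clinical <- validate_clinical(clinical)
  common <- intersect(colnames(expr), clinical$sample)
  dropped <- setdiff(union(colnames(expr), clinical$sample), common)
  if (length(dropped) > 0L)
    message("align_cohort: dropping ", length(dropped),
            " sample(s) absent from one input")
  clinical <- clinical[match(common, clinical$sample), , drop = FALSE]
  expr <- expr[, common, drop = FALSE]
  healthy <- clinical$sample[clinical$tissue == "healthy"]
  tumor <- clinical$sample[clinical$tissue == "tumor"]
  if (length(healthy) == 0L)
    stop("cohort has no healthy samples; hypoxia baseline impossible")
  if (length(tumor) == 0L)
    stop("cohort has no tumor samples")
  structure(list(expr = expr, clinical = clinical,
                 healthy_ids = healthy, tumor_ids = tumor),
            class = "lnc_cohort")
}

#' @export
print.lnc_cohort <- function(x, ...) {
  cat("lnc_cohort:", nrow(x$expr), "genes x", ncol(x$expr), "samples (",
      length(x$healthy_ids), "healthy,", length(x$tumor_ids), "tumor )\n")
  n_surv <- sum(!is.na(x$clinical$os_time) & !is.na(x$clinical$os_event) &
                  x$clinical$tissue == "tumor")
  cat("  tumors with survival data:", n_surv, "\n")
  invisible(x)
}

#' Create a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of gene identifiers (exact-match, case
#'   sensitive; no alias resolution is attempted).
#' @return An object of class `gene_signature` with fields `name`, `genes`,
#'   `expected_size`.
#' @export
gene_signature <- function(name, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("signature '", name, "' contains duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (length(genes) == 0L) stop("signature '", name, "' is empty")
  structure(list(name = name, genes = genes, expected_size = length(genes)),
            class = "gene_signature")
}

#' Read a gene signature file
#'
#' Format: first line is a header naming the signature (prefixed `#` or not),
#' then one gene identifier per line.
#'
#' @param path Path to the signature file.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("signature file needs a header line and >= 1 gene: ", path)
  name <- sub("^#\\s*", "", trimws(lines[1L]))
  gene_signature(name, trimws(lines[-1L]))
}

#' Write a gene signature file
#' @param sig A [gene_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  writeLines(c(paste0("# ", sig$name), sig$genes), path)
  invisible(path)
}

#' Path to a signature fixture shipped with the package
#'
#' Available fixtures: `"hypoxia_metagene_27"` (the 27-gene hypoxia metagene
#' used for the count score), `"stroma_141"` and `"immune_141"` (141-gene
#' stroma and immune content signatures for cumulative z-scores). Gene
#' identities in these files are configurable stand-ins with the documented
#' sizes and biology; swap in project-specific lists via [read_signature()].
#'
#' @param name Fixture name (without extension).
#' @return Absolute path to the installed fixture file.
#' @export
signature_fixture <- function(name = c("hypoxia_metagene_27", "stroma_141", "immune_141")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".txt"), package = "lncscreen")
  if (!nzchar(path)) stop("fixture not found: ", name)
  path
}

#' Samples usable for survival analysis
#'
#' Tumor samples with non-missing overall-survival time and event indicator.
#' @param cohort An `lnc_cohort`.
#' @return Character vector of sample ids.
#' @export
survival_samples <- function(cohort) {
  cl <- cohort$clinical
  keep <- cl$tissue == "tumor" & !is.na(cl$os_time) & !is.na(cl$os_event)
  n_dropped <- sum(cl$tissue == "tumor") - sum(keep)
  if (n_dropped > 0L)
    message("excluding ", n_dropped, " tumor sample(s) without survival data")
  cl$sample[keep]
}
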