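# Small in-code fixtures shared across test files.

# write a matrix as TSV and return the path
write_tsv_matrix <- function(mat, path = tempfile(fileext = ".tsv")) {
  write_expression_matrix(mat, path)
  path
}

toy_matrix <- function(genes = c("G1", "G2", "G3"), samples = c("S1", "S2"),
                       values = seq_len(length(genes) * length(samples))) {
  matrix(values, nrow = length(genes), dimnames = list(genes, samples))
}

toy_clinical <- function(samples, tissue, os_time = NULL, os_event = NULL,
                         recurrence = NA, stage = NA) {
  n <- length(samples)
  data.frame(sample = samples, tissue = tissue,
             os_time = if (is.null(os_time)) rep(NA_real_, n) else os_time,
             os_event = if (is.null(os_event)) rep(NA_integer_, n) else os_event,
             recurrence = rep(recurrence, length.out = n),
             stage = rep(stage, length.out = n),
             stringsAsFactors = FALSE)
}

# minimal aligned cohort: n_h healthy + n_t tumor samples over a gene matrix
toy_cohort <- function(expr, n_h, n_t, os_time = NULL, os_event = NULL,
                       recurrence = NA) {
  samples <- colnames(expr)
  stopifnot(length(samples) == n_h + n_t)
  clin <- toy_clinical(samples,
                       tissue = c(rep("healthy", n_h), rep("tumor", n_t)),
                       os_time = c(rep(NA_real_, n_h),
                                   if (is.null(os_time)) rep(NA_real_, n_t) else os_time),
                       os_event = c(rep(NA_integer_, n_h),
                                    if (is.null(os_event)) rep(NA_integer_, n_t) else os_event),
                       recurrence = recurrence)
  suppressMessages(align_cohort(expr, clin))
}

# a tiny sc_matrix with explicit counts and one cluster label per cell
toy_sc <- function(counts, clusters) {
  ann <- data.frame(barcode = colnames(counts), cluster = clusters,
                    stringsAsFactors = FALSE)
  sc_matrix(counts, ann)
}

# brute-force BH step-up, straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}
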