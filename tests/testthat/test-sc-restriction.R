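# dense toy counts: 5 genes x 6 cells across 2 clusters
toy_counts <- function() {
  m <- matrix(c(10, 0, 0, 0, 0, 0,
                0, 5, 5, 5, 5, 5,
                1, 1, 1, 1, 1, 1,
                2, 2, 2, 0, 0, 0,
                0, 0, 0, 3, 3, 3), nrow = 5, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC", "GD", "GE"),
                              sprintf("C%d", 1:6)))
  m
}

test_that("QC boundaries follow the quoted rules strictly", {
  set.seed(1)
  n_genes <- 400
  genes <- c(paste0("MT-", 1:4), sprintf("G%03d", seq_len(n_genes - 4)))
  # five cells: normal, low-feature (150 detected), boundary-200, mito 10%,
  # mito exactly 5%
  counts <- matrix(0L, n_genes, 5, dimnames = list(genes, sprintf("C%d", 1:5)))
  counts[5:304, 1] <- 1L                       # 300 features
  counts[5:154, 2] <- 1L                       # 150 features -> removed
  counts[5:204, 3] <- 1L                       # exactly 200 -> retained
  counts[5:303, 4] <- 1L; counts[1, 4] <- 34L  # 34/333 > 10% mito (300 features)
  counts[5:289, 5] <- 1L; counts[1:4, 5] <- c(5L, 5L, 5L, 0L)  # 15/300 = 5% exactly -> retained
  sc <- toy_sc(counts, rep("K", 5))
  filt <- qc_filter(sc, min_cells = 1)
  kept <- colnames(filt$counts)
  expect_true(all(c("C1", "C3", "C5") %in% kept))
  expect_false("C2" %in% kept)
  expect_false("C4" %in% kept)
  rep <- attr(filt, "qc_report")
  expect_identical(rep$removed_low_features, "C2")
  expect_identical(rep$removed_high_mito, "C4")
})

test_that("ribosomal and rare genes are removed by their rules", {
  genes <- c("RPL3", "RPS7", "GOK1", "GRARE")
  counts <- matrix(5L, 4, 4, dimnames = list(genes, sprintf("C%d", 1:4)))
  counts["GRARE", ] <- c(1L, 1L, 0L, 0L)   # in 2 cells < 3
  sc <- toy_sc(counts, rep("K", 4))
  filt <- qc_filter(sc, min_features = 1)
  expect_identical(rownames(filt$counts), "GOK1")
  rep <- attr(filt, "qc_report")
  expect_equal(rep$genes_ribosomal, 2L)
  expect_equal(rep$genes_rare, 1L)
})

test_that("a matrix violating no rule passes through unchanged; qc is idempotent", {
  set.seed(2)
  counts <- matrix(rpois(500 * 8, 3), 500, 8,
                   dimnames = list(sprintf("G%03d", 1:500), sprintf("C%d", 1:8)))
  sc <- toy_sc(counts, rep(c("a", "b"), 4))
  filt <- qc_filter(sc, min_features = 100)
  expect_identical(as.matrix(filt$counts), as.matrix(sc$counts))
  filt2 <- qc_filter(filt, min_features = 100)
  expect_identical(as.matrix(filt2$counts), as.matrix(filt$counts))
  # idempotence on a matrix that does get filtered
  big <- simulate_sc(sim_params(sc_n_cells = 300, sc_n_genes = 8000), seed = 4)
  f1 <- qc_filter(big$sc)
  f2 <- qc_filter(f1)
  expect_identical(as.matrix(f1$counts), as.matrix(f2$counts))
})

test_that("normalization matches hand arithmetic and is cell-scale invariant", {
  counts <- matrix(c(10, 0, 0,
                     0, 2, 4,
                     0, 3, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("G1", "G2", "G3"), c("C1", "C2", "C3")))
  sc <- toy_sc(counts, rep("k", 3))
  norm <- normalize_log(sc)
  # cell C1: library 10, single gene count 10 -> log1p(10 * 1e4 / 10)
  expect_equal(norm["G1", "C1"], log1p(10000), tolerance = 1e-9)
  expected <- log1p(t(t(counts) / colSums(counts)) * 1e4)
  expect_equal(as.matrix(norm), expected, tolerance = 1e-9)
  # doubling all counts of a cell changes nothing
  counts2 <- counts; counts2[, 2] <- counts2[, 2] * 2
  norm2 <- normalize_log(toy_sc(counts2, rep("k", 3)))
  expect_equal(norm2[, "C2"], norm[, "C2"], tolerance = 1e-12)
  # zero-count cells are rejected
  counts3 <- counts; counts3[, 3] <- 0
  expect_error(normalize_log(toy_sc(counts3, rep("k", 3))), "zero-count")
})

test_that("cluster summaries report means, detection fractions and sizes", {
  counts <- toy_counts()
  sc <- toy_sc(counts, c("X", "X", "X", "Y", "Y", "Y"))
  norm <- normalize_log(sc, log = FALSE)
  cs <- cluster_summary(norm, sc$cells$cluster, "GD")
  expect_equal(cs$n_cells, c(3L, 3L))
  expect_equal(cs$detection_fraction, c(1, 0))
  expect_equal(cs$mean_expr[cs$cluster == "Y"], 0)
  expect_error(cluster_summary(norm, sc$cells$cluster, "NOPE"), "NOPE")
  expect_error(cluster_summary(norm, c("X", "Y"), "GD"), "cover")
  # single cluster: summary equals the global mean / fraction
  cs1 <- cluster_summary(norm, rep("all", 6), "GB")
  expect_equal(cs1$mean_expr, mean(norm["GB", ]))
  expect_equal(cs1$detection_fraction, mean(norm["GB", ] > 0))
  # gene present in the matrix but expressed nowhere
  counts0 <- rbind(counts, GZ = 0L)
  norm0 <- normalize_log(toy_sc(counts0, rep(c("X", "Y"), each = 3)), log = FALSE)
  cs0 <- cluster_summary(norm0, rep(c("X", "Y"), each = 3), "GZ")
  expect_true(all(cs0$mean_expr == 0) && all(cs0$detection_fraction == 0))
})

test_that("restriction score is 1 under confinement and 1/k under uniformity", {
  prof <- function(means) {
    s <- data.frame(cluster = sprintf("K%d", seq_along(means)),
                    mean_expr = means,
                    detection_fraction = as.numeric(means > 0),
                    n_cells = 10L)
    attr(s, "gene") <- "q"
    class(s) <- c("cluster_summary", "data.frame")
    s
  }
  conf <- restriction_score(prof(c(0, 0, 4, 0, 0)))
  expect_equal(conf$score, 1)
  expect_equal(conf$fold_next, Inf)
  expect_true(conf$restricted)
  unif <- restriction_score(prof(rep(2, 5)))
  expect_equal(unif$score, 0.2)
  expect_false(unif$restricted)
  zero <- restriction_score(prof(rep(0, 5)))
  expect_true(zero$undefined)
  expect_error(restriction_score(prof(3)), ">= 2 clusters")
})

test_that("restriction is invariant to cluster relabeling and global scaling", {
  set.seed(9)
  means <- c(8, 0.3, 0.5, 0.2)
  prof <- function(m, labels) {
    s <- data.frame(cluster = labels, mean_expr = m,
                    detection_fraction = 0.5, n_cells = 10L)
    attr(s, "gene") <- "q"
    class(s) <- c("cluster_summary", "data.frame")
    s
  }
  base <- restriction_score(prof(means, c("a", "b", "c", "d")))
  relab <- restriction_score(prof(means, c("w", "x", "y", "z")))
  scaled <- restriction_score(prof(means * 7, c("a", "b", "c", "d")))
  expect_equal(base$score, relab$score)
  expect_equal(base$score, scaled$score)
  expect_equal(base$fold_next, scaled$fold_next)
})

test_that("marker concordance approaches 1 as noise vanishes", {
  set.seed(12)
  base_prof <- c(10, 0.1, 0.1, 0.1, 0.1)
  mk <- function(m) {
    s <- data.frame(cluster = sprintf("K%d", 1:5), mean_expr = m,
                    detection_fraction = 0.5, n_cells = 10L)
    attr(s, "gene") <- "g"
    class(s) <- c("cluster_summary", "data.frame")
    s
  }
  q <- mk(base_prof + rnorm(5, sd = 0.01))
  rs <- restriction_score(q, list(marker = mk(base_prof)))
  expect_gt(rs$concordance[["marker"]], 0.999)
})

test_that("the MTX triplet reader reconstructs the matrix and annotations", {
  counts <- toy_counts()
  d <- tempfile(); dir.create(d)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), file.path(d, "m.mtx"))
  writeLines(rownames(counts), file.path(d, "features.tsv"))
  writeLines(colnames(counts), file.path(d, "barcodes.tsv"))
  ann <- data.frame(barcode = colnames(counts),
                    cluster = rep(c("X", "Y"), each = 3))
  write.table(ann, file.path(d, "ann.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  sc <- read_sc_mtx(file.path(d, "m.mtx"), file.path(d, "features.tsv"),
                    file.path(d, "barcodes.tsv"), file.path(d, "ann.tsv"))
  expect_equal(as.matrix(sc$counts), counts)
  expect_identical(sc$cells$cluster, ann$cluster)
})
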