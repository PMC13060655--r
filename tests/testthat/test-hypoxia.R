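test_that("fold changes are linear-scale ratios over the mean healthy baseline", {
  # healthy log2 {3, 5} -> linear {8, 32}, mean 20; tumor log2(40.2) -> FC 2.01
  expr <- matrix(c(3, 5, log2(40.2)), nrow = 1,
                 dimnames = list("HG1", c("H1", "H2", "T1")))
  co <- toy_cohort(expr, 2, 1)
  sig <- gene_signature("s", "HG1")
  fct <- compute_fold_changes(co, sig)
  expect_equal(unname(fct$baseline), 20)
  expect_equal(unname(fct$fc["HG1", "T1"]), 40.2 / 20, tolerance = 1e-12)
})

test_that("tumor equal to the healthy mean gives FC 1 everywhere", {
  expr <- matrix(log2(c(10, 10, 10, 20, 20, 20)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("HG1", "HG2"), c("H1", "H2", "T1")))
  co <- toy_cohort(expr, 2, 1)
  fct <- compute_fold_changes(co, gene_signature("s", c("HG1", "HG2")))
  expect_equal(unname(fct$fc[, "T1"]), c(1, 1))
})

test_that("missing signature genes error at full required coverage", {
  expr <- matrix(1:6, nrow = 2, dimnames = list(c("HG1", "HG2"), c("H1", "T1", "T2")))
  co <- toy_cohort(expr, 1, 2)
  sig <- gene_signature("s", c("HG1", "HG2", "HGMISSING"))
  expect_error(compute_fold_changes(co, sig, min_coverage = 1), "HGMISSING")
  expect_message(fct <- compute_fold_changes(co, sig, min_coverage = 0.5),
                 "absent")
  expect_setequal(fct$genes_missing, "HGMISSING")
})

test_that("score counts strict FC > 2 and classifies by the 15-of-27 boundary", {
  # 27-gene signature; tumor A passes 14 genes, tumor B passes 15
  sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  genes <- sig$genes
  healthy <- matrix(3, nrow = 27, ncol = 2,
                    dimnames = list(genes, c("H1", "H2")))
  tA <- ifelse(seq_len(27) <= 14, 3 + log2(2.5), 3)   # FC 2.5 for 14 genes
  tB <- ifelse(seq_len(27) <= 15, 3 + log2(2.5), 3)
  tC <- rep(3 + 1, 27)                                # FC exactly 2.0 everywhere
  expr <- cbind(healthy, A = tA, B = tB, C = tC)
  co <- toy_cohort(expr, 2, 3)
  scores <- hypoxia_score(compute_fold_changes(co, sig))
  expect_equal(scores$score[scores$sample == "A"], 14L)
  expect_equal(as.character(scores$class[scores$sample == "A"]), "Low")
  expect_equal(scores$score[scores$sample == "B"], 15L)
  expect_equal(as.character(scores$class[scores$sample == "B"]), "High")
  # FC exactly 2 is not counted (strict inequality), score 0 classifies Low
  expect_equal(scores$score[scores$sample == "C"], 0L)
  expect_equal(as.character(scores$class[scores$sample == "C"]), "Low")
})

test_that("the High threshold rescales proportionally with partial signatures", {
  sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  genes <- sig$genes[1:22]  # 22 of 27 present -> threshold ceil(15*22/27) = 13
  healthy <- matrix(3, nrow = 22, ncol = 2, dimnames = list(genes, c("H1", "H2")))
  tA <- c(rep(3 + 2, 12), rep(3, 10))
  tB <- c(rep(3 + 2, 13), rep(3, 9))
  co <- toy_cohort(cbind(healthy, A = tA, B = tB), 2, 2)
  fct <- suppressMessages(compute_fold_changes(co, sig))
  expect_message(scores <- hypoxia_score(fct), "rescaled 15 -> 13")
  expect_equal(as.character(scores$class), c("Low", "High"))
})

test_that("raising a tumor expression value never decreases its score", {
  sim <- simulate_cohort(sim_params(n_healthy = 4, n_tumor = 10, n_decoys = 0),
                         seed = 3)
  sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  sc0 <- hypoxia_score(compute_fold_changes(sim$cohort, sig))
  for (g in sample(sig$genes, 5)) {
    co2 <- sim$cohort
    co2$expr[g, co2$tumor_ids[1]] <- co2$expr[g, co2$tumor_ids[1]] + 3
    sc2 <- hypoxia_score(compute_fold_changes(co2, sig))
    expect_gte(sc2$score[1], sc0$score[1])
  }
})

test_that("score is invariant to sample order", {
  sim <- simulate_cohort(sim_params(n_healthy = 4, n_tumor = 12, n_decoys = 0),
                         seed = 5)
  sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  sc1 <- hypoxia_score(compute_fold_changes(sim$cohort, sig))
  perm <- sample(ncol(sim$cohort$expr))
  co2 <- suppressMessages(align_cohort(sim$cohort$expr[, perm],
                                       sim$cohort$clinical))
  sc2 <- hypoxia_score(compute_fold_changes(co2, sig))
  m <- match(sc1$sample, sc2$sample)
  expect_identical(sc1$score, sc2$score[m])
})

test_that("spearman association is exact on monotone and tied fixtures", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  st <- spearman_test(x, x^3)       # monotone transform
  expect_equal(st$rho, 1)
  # 6-point pair with one tie: oracle = Pearson formula on hand-assigned mid-ranks
  a <- c(1.0, 2.0, 2.0, 3.0, 4.0, 5.0)   # ranks 1, 2.5, 2.5, 4, 5, 6
  b <- c(2.0, 1.0, 4.0, 3.0, 6.0, 5.0)   # ranks 2, 1, 4, 3, 6, 5
  ra <- c(1, 2.5, 2.5, 4, 5, 6); rb <- c(2, 1, 4, 3, 6, 5)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  st <- spearman_test(a, b)
  expect_equal(st$rho, oracle, tolerance = 1e-12)
  # agreement with the reference implementation at the t-approximation
  ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  expect_equal(st$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("zero-variance vectors are flagged undefined rather than rho = 0", {
  st <- spearman_test(rep(2, 6), c(1, 2, 3, 4, 5, 6))
  expect_true(st$undefined)
  expect_true(is.na(st$rho))
})

test_that("spearman p-values are calibrated under the null", {
  set.seed(11)
  n <- 20; reps <- 2000
  rhos <- numeric(reps); ps <- numeric(reps)
  for (i in seq_len(reps)) {
    st <- spearman_test(rnorm(n), rnorm(n))
    rhos[i] <- st$rho; ps[i] <- st$p_value
  }
  expect_lt(abs(mean(rhos)), 0.05)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("the screen matches the single-transcript path and BH-adjusts", {
  sim <- simulate_cohort(sim_params(n_healthy = 4, n_tumor = 30, n_decoys = 10),
                         seed = 9)
  sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  scores <- hypoxia_score(compute_fold_changes(sim$cohort, sig))
  trs <- sim$truth$transcripts$transcript
  scr <- hypoxia_association_screen(sim$cohort, trs, scores)
  one <- hypoxia_association(sim$cohort, trs[3], scores)
  expect_equal(scr$rho[3], one$rho, tolerance = 1e-12)
  expect_equal(scr$p_value[3], one$p_value, tolerance = 1e-12)
  expect_equal(scr$adj_p, bh_adjust(scr$p_value))
  expect_error(hypoxia_association_screen(sim$cohort, "NOPE", scores), "NOPE")
})
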