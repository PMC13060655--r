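make_criteria <- function(transcript, fh, fo, fi, rho = 0.5,
                          adj_p = seq_along(transcript) / 100) {
  out <- data.frame(transcript = transcript,
                    hypoxia_rho = rho, hypoxia_p = adj_p / 2,
                    hypoxia_adj_p = adj_p,
                    flag_hypoxia = fh, flag_os = fo, flag_invitro = fi,
                    direction = ifelse(fh, ifelse(rho > 0, "positive", "negative"),
                                       NA_character_),
                    missing = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("candidate_criteria", "data.frame")
  out
}

test_that("set algebra over hand-enumerated flags matches by hand", {
  cc <- make_criteria(c("t1", "t2", "t3"),
                      fh = c(TRUE, FALSE, TRUE),
                      fo = c(TRUE, TRUE, TRUE),
                      fi = c(FALSE, TRUE, TRUE))
  sets <- intersect_candidates(cc)
  expect_identical(sets$sets$triple, "t3")
  expect_equal(sets$counts$hypoxia_os, 2L)
  expect_equal(sets$counts$os_invitro, 2L)
  expect_equal(sets$counts$hypoxia_invitro, 1L)
  expect_identical(sets$final$transcript, "t3")
})

test_that("all-false flags give empty sets", {
  cc <- make_criteria(c("a", "b"), fh = FALSE, fo = FALSE, fi = FALSE)
  sets <- intersect_candidates(cc)
  expect_true(all(vapply(sets$sets, length, integer(1)) == 0L))
})

test_that("Venn counts respect inclusion-exclusion on random flag tables", {
  set.seed(17)
  for (i in 1:20) {
    n <- 50
    cc <- make_criteria(sprintf("t%02d", 1:n),
                        fh = runif(n) < 0.4, fo = runif(n) < 0.4,
                        fi = runif(n) < 0.4)
    s <- intersect_candidates(cc)
    expect_true(length(s$sets$triple) <= min(s$counts$hypoxia_os,
                                             s$counts$hypoxia_invitro,
                                             s$counts$os_invitro))
    expect_true(all(s$sets$triple %in% s$sets$hypoxia_os))
    # |A u B u C| by inclusion-exclusion equals the direct union
    union_size <- length(unique(c(s$sets$hypoxia, s$sets$os, s$sets$invitro)))
    ie <- s$counts$hypoxia + s$counts$os + s$counts$invitro -
      s$counts$hypoxia_os - s$counts$hypoxia_invitro - s$counts$os_invitro +
      s$counts$triple
    expect_equal(union_size, ie)
  }
})

test_that("screen_config presets carry the documented thresholds and reject unknowns", {
  strict <- screen_config()
  expect_equal(strict$hypoxia_adj_p, 0.001)
  expect_true(is.na(strict$ratio_fold))
  loose <- screen_config("methods-loose")
  expect_equal(loose$hypoxia_adj_p, 0.05)
  expect_equal(loose$ratio_fold, 1.6)
  expect_equal(loose$ratio_fdr, 0.05)
  expect_error(screen_config(bogus = 1), "bogus")
})

test_that("evaluate_criteria flags the planted candidate and only it", {
  sim <- simulate_cohort(sim_params(n_tumor = 200, n_decoys = 100), seed = 23)
  sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  scores <- hypoxia_score(compute_fold_changes(sim$cohort, sig))
  iv <- simulate_invitro(sim_params(n_decoys = 100), seed = 23)
  de <- two_group_de(iv$expr, iv$normoxia_ids, iv$hypoxia_ids)
  trs <- sim$truth$transcripts$transcript
  cc <- suppressMessages(evaluate_criteria(sim$cohort, scores, de, trs))
  cand <- cc[cc$transcript == "LNC0001", ]
  expect_true(cand$flag_hypoxia && cand$flag_os && cand$flag_invitro)
  expect_identical(cand$direction, "positive")
  sets <- intersect_candidates(cc)
  expect_identical(sets$final$transcript, "LNC0001")
  # flags are pure functions of statistics + thresholds: a vacuous threshold
  # config switches every hypoxia flag off
  cc0 <- suppressMessages(evaluate_criteria(sim$cohort, scores, de, trs,
                                            screen_config(hypoxia_adj_p = 0)))
  expect_false(any(cc0$flag_hypoxia))
  expect_true(all(is.na(cc0$direction)))
})

test_that("a transcript absent from an input is flagged missing, not false", {
  sim <- simulate_cohort(sim_params(n_tumor = 30, n_decoys = 5), seed = 3)
  sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  scores <- hypoxia_score(compute_fold_changes(sim$cohort, sig))
  iv <- simulate_invitro(sim_params(n_decoys = 5), seed = 3)
  de <- two_group_de(iv$expr, iv$normoxia_ids, iv$hypoxia_ids)
  trs <- c(sim$truth$transcripts$transcript, "LNC_NOT_MEASURED")
  expect_message(cc <- evaluate_criteria(sim$cohort, scores, de, trs), "missing")
  row <- cc[cc$transcript == "LNC_NOT_MEASURED", ]
  expect_true(row$missing)
  expect_false(row$flag_hypoxia || row$flag_os || row$flag_invitro)
  sets <- intersect_candidates(cc)
  expect_false("LNC_NOT_MEASURED" %in% unlist(sets$sets))
  expect_equal(sets$counts$n_screened, length(trs) - 1L)
})

test_that("the screen is deterministic for identical inputs and config", {
  sim <- simulate_cohort(sim_params(n_tumor = 40, n_decoys = 20), seed = 5)
  sig <- read_signature(signature_fixture("hypoxia_metagene_27"))
  scores <- hypoxia_score(compute_fold_changes(sim$cohort, sig))
  iv <- simulate_invitro(sim_params(n_decoys = 20), seed = 5)
  de <- two_group_de(iv$expr, iv$normoxia_ids, iv$hypoxia_ids)
  trs <- sim$truth$transcripts$transcript
  cc1 <- suppressMessages(evaluate_criteria(sim$cohort, scores, de, trs))
  cc2 <- suppressMessages(evaluate_criteria(sim$cohort, scores, de, trs))
  expect_identical(cc1, cc2)
  expect_identical(intersect_candidates(cc1)$final$transcript,
                   intersect_candidates(cc2)$final$transcript)
})
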