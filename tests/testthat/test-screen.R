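test_that("control baseline is the per-feature mean over controls", {
  m <- matrix(c(2, 4, 1, 0, 0, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("c1", "c2", "p1")))
  em <- make_expr(m)
  b <- control_baseline(em, c("c1", "c2"))
  expect_equal(unname(b["f1"]), 3)
  expect_equal(unname(b["f2"]), 0)
  expect_equal(unname(control_baseline(em, "c1")["f1"]), 2)
  expect_error(control_baseline(em, character()), "empty")
})

test_that("step 2 keeps pairs strictly above the upstream percentile", {
  genes <- gene_models(paste0("u", 1:4), "chr1",
                       c(0, 200, 400, 600) * 10,
                       c(0, 200, 400, 600) * 10 + 100, rep("+", 4))
  pairs <- data.frame(pair_id = paste0("pr", 1:4),
                      upstream_gene = paste0("u", 1:4),
                      downstream_gene = paste0("u", c(2, 3, 4, 1)))
  m <- matrix(c(0, 1, 2, 3), ncol = 1, dimnames = list(paste0("u", 1:4), "p1"))
  em <- make_expr(m)
  ## linear-interpolation 25th percentile of {0,1,2,3} = 0.75
  kept <- step2_expressed_upstream(pairs, em, "p1")
  expect_setequal(kept$pair_id, c("pr2", "pr3", "pr4"))
  ## all equal: nothing is strictly above the percentile
  em2 <- make_expr(matrix(2, 4, 1, dimnames = list(paste0("u", 1:4), "p1")))
  expect_equal(nrow(step2_expressed_upstream(pairs, em2, "p1")), 0L)
  ## a single pair can never beat its own percentile
  expect_equal(nrow(step2_expressed_upstream(pairs[1, ], em, "p1")), 0L)
})

test_that("step 3 applies the strict intergenic fold-change rule", {
  mk <- function(patient_ig, ctl_ig) {
    m <- matrix(c(patient_ig, ctl_ig, ctl_ig), nrow = 1,
                dimnames = list("pr1", c("p1", "c1", "c2")))
    em <- make_expr(m)
    list(em = em, b = control_baseline(em, c("c1", "c2")))
  }
  pair <- data.frame(pair_id = "pr1", upstream_gene = "u", downstream_gene = "d")
  x <- mk(12, 2)
  r <- step3_intergenic_fc(pair, x$em, "p1", x$b)
  expect_true(r$passed); expect_equal(r$fc, 6)
  x <- mk(9, 2)
  r <- step3_intergenic_fc(pair, x$em, "p1", x$b)
  expect_false(r$passed); expect_equal(r$fc, 4.5)
  ## zero control mean, zero patient signal: fail
  x <- mk(0, 0)
  expect_false(step3_intergenic_fc(pair, x$em, "p1", x$b)$passed)
  ## zero control mean, nonzero patient: fallback-unit policy
  x <- mk(3, 0)
  expect_true(step3_intergenic_fc(pair, x$em, "p1", x$b, fallback_unit = 0.5)$passed)
  expect_false(step3_intergenic_fc(pair, x$em, "p1", x$b, fallback_unit = 1)$passed)
  ## pseudocount policy instead
  pp <- screen_params(zero_mean_epsilon = 0.1)
  r <- step3_intergenic_fc(pair, x$em, "p1", x$b, params = pp)
  expect_equal(r$fc, 30)
  expect_true(r$passed)
})

test_that("step 4 switches between absolute and fold branches on zero control mean", {
  mk <- function(patient_dn, ctl_dn) {
    m <- matrix(c(patient_dn, ctl_dn, ctl_dn), nrow = 1,
                dimnames = list("d", c("p1", "c1", "c2")))
    em <- make_expr(m)
    list(em = em, b = control_baseline(em, c("c1", "c2")))
  }
  pair <- data.frame(pair_id = "pr1", upstream_gene = "u", downstream_gene = "d")
  x <- mk(2, 0)
  r <- step4_downstream_effect(pair, x$em, "p1", x$b)
  expect_true(r$passed); expect_equal(r$branch, "absolute"); expect_equal(r$value, 2)
  x <- mk(1.4, 1)
  r <- step4_downstream_effect(pair, x$em, "p1", x$b)
  expect_false(r$passed); expect_equal(r$branch, "fold"); expect_equal(r$value, 1.4)
  x <- mk(4, 2)
  r <- step4_downstream_effect(pair, x$em, "p1", x$b)
  expect_true(r$passed); expect_equal(r$value, 2)
})

test_that("a hand-planted event produces exactly one positive call", {
  fx <- toy_screen_fixture()
  calls <- call_trt(fx$pairs, fx$expr, c("P1", "P2"), c("C1", "C2"))
  expect_equal(sum(calls$calls), 1L)
  expect_true(calls$calls[fx$planted_pair, "P1"])
  ## step-by-step agreement for the planted cell
  b <- control_baseline(fx$expr, c("C1", "C2"))
  pr <- fx$pairs[fx$pairs$pair_id == fx$planted_pair, ]
  s2 <- fx$planted_pair %in%
    step2_expressed_upstream(fx$pairs, fx$expr, "P1")$pair_id
  s3 <- step3_intergenic_fc(pr, fx$expr, "P1", b, all_pairs = fx$pairs)$passed
  s4 <- step4_downstream_effect(pr, fx$expr, "P1", b)$passed
  expect_true(s2 && s3 && s4)
  ## diagnostics row mirrors the matrix
  d <- calls$diagnostics
  cell <- d[d$pair_id == fx$planted_pair & d$patient_id == "P1", ]
  expect_true(cell$call)
  expect_equal(cell$intergenic_fc, 12)
})

test_that("all-zero expression produces an all-false call matrix", {
  fx <- toy_screen_fixture()
  zero <- make_expr(matrix(0, nrow(fx$expr$fpkm), 4,
                           dimnames = dimnames(fx$expr$fpkm)))
  calls <- call_trt(fx$pairs, zero, c("P1", "P2"), c("C1", "C2"))
  expect_false(any(calls$calls))
})

test_that("raising any threshold never adds calls (nested call sets)", {
  co <- simulate_trt_cohort(sim_preset("default", seed = 3,
                                       n_chromosomes = 2L,
                                       genes_per_chromosome = 60L,
                                       n_patients = 10L, n_controls = 6L,
                                       n_trt_pairs_planted = 15L))
  gt <- co$ground_truth
  base <- call_trt(co$pairs, co$expr, gt$patient_ids, gt$control_ids)
  harder <- list(
    screen_params(intergenic_fc_min = 10),
    screen_params(downstream_fc_min = 3),
    screen_params(downstream_abs_min = 3),
    screen_params(upstream_percentile = 50))
  for (p in harder) {
    res <- call_trt(co$pairs, co$expr, gt$patient_ids, gt$control_ids, p)
    expect_true(all(base$calls | !res$calls))  # res subset of base
  }
})

test_that("patient order only permutes call-matrix columns", {
  fx <- toy_screen_fixture()
  a <- call_trt(fx$pairs, fx$expr, c("P1", "P2"), c("C1", "C2"))
  b <- call_trt(fx$pairs, fx$expr, c("P2", "P1"), c("C1", "C2"))
  expect_identical(a$calls, b$calls[, c("P1", "P2")])
})

test_that("controls screened against their own baseline are not called", {
  co <- simulate_trt_cohort(sim_preset("default", seed = 9,
                                       n_chromosomes = 2L,
                                       genes_per_chromosome = 60L,
                                       n_patients = 6L, n_controls = 10L,
                                       n_trt_pairs_planted = 10L))
  gt <- co$ground_truth
  half <- gt$control_ids[1:5]
  rest <- gt$control_ids[6:10]
  calls <- call_trt(co$pairs, co$expr, half, rest)
  expect_lte(mean(calls$calls), 0.005)
})

test_that("recurrence selection is strictly greater-than", {
  calls <- structure(list(
    calls = matrix(c(rep(TRUE, 4), rep(FALSE, 6),
                     rep(TRUE, 3), rep(FALSE, 7)), nrow = 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), paste0("p", 1:10))),
    params = screen_params()), class = "trt_calls")
  calls$recurrence <- rowMeans(calls$calls)
  expect_equal(recurrent_pairs(calls), "a")      # 0.4 > 0.3 kept; 0.3 not
  empty <- structure(list(calls = matrix(FALSE, 0, 3), recurrence = numeric(),
                          params = screen_params()), class = "trt_calls")
  expect_length(recurrent_pairs(empty), 0L)
})
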