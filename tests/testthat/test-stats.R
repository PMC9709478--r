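test_that("Wilcoxon comparison matches exact enumeration for tiny groups", {
  x <- c(1, 2, 3); y <- c(101, 102, 103)
  r <- compare_burden_groups(c(x, y), rep(c("a", "b"), each = 3))
  expect_true(r$exact)
  ## full enumeration over the 20 rank assignments gives the minimal
  ## two-sided p for n = 3 + 3
  expect_equal(r$p, wilcoxon_exact_oracle(x, y))
  expect_equal(r$p, 0.1)
  ## further random small instances against the enumeration oracle
  set.seed(5)
  for (i in 1:10) {
    v <- sample(1:1000, 8)
    lab <- rep(c("g1", "g2"), each = 4)
    r <- compare_burden_groups(v, lab)
    expect_equal(r$p, wilcoxon_exact_oracle(v[1:4], v[5:8]))
  }
})

test_that("Wilcoxon p is label-symmetric and near 1 for identical groups", {
  v <- c(1, 2, 3, 4, 5, 6)
  a <- compare_burden_groups(v, rep(c("x", "y"), 3))
  b <- compare_burden_groups(v, rep(c("y", "x"), 3))
  expect_equal(a$p, b$p)
  same <- compare_burden_groups(rep(c(5, 7, 9), 2), rep(c("x", "y"), each = 3))
  expect_gte(same$p, 0.9)
  expect_error(compare_burden_groups(1:3, rep("x", 3)), "two")
})

test_that("Spearman correlation matches the explicit rank oracle", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    x <- rnorm(n)
    y <- if (i %% 2) rnorm(n) else sample(1:3, n, replace = TRUE)  # with ties
    s <- correlate_burden_trait(x, y)
    expect_equal(s$rho, spearman_rank_oracle(x, y), tolerance = 1e-12)
  }
  ## perfect monotone / constant cases
  expect_equal(correlate_burden_trait(1:6, (1:6)^3)$rho, 1)
  expect_true(is.na(correlate_burden_trait(1:5, rep(2, 5))$rho))
  expect_error(correlate_burden_trait(1:2, 1:2), "fewer than 3")
  ## missing trait values are dropped pairwise
  s <- correlate_burden_trait(1:5, c(2, 4, NA, 8, 10))
  expect_equal(s$n, 4)
  expect_equal(s$rho, 1)
})

test_that("chi-square statistic matches the hand-computed sum of (O-E)^2/E", {
  r <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  ## hand computation for [[20,5],[5,20]]: all E = 12.5,
  ## (O-E)^2/E = 56.25/12.5 = 4.5 per cell, statistic = 18
  tab <- matrix(c(20, 5, 5, 20), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - E)^2 / E)
  expect_equal(hand, 18)
  r <- chi_square_2x2(tab, correct = FALSE)
  expect_equal(r$statistic, hand)
  ## transposition invariance
  expect_equal(chi_square_2x2(t(tab))$statistic, r$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("burden counts the union of cis and trans events once", {
  mk_calls <- function(ids, up, dn, m) {
    structure(list(calls = m,
                   pairs = data.frame(pair_id = ids, upstream_gene = up,
                                      downstream_gene = dn),
                   params = screen_params()), class = "trt_calls")
  }
  pats <- c("p1", "p2")
  cis <- mk_calls(c("c1", "c2", "c3"), c("a", "b", "c"), c("b", "c", "d"),
                  matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 3, 2,
                         dimnames = list(NULL, pats)))
  ## trans pair over the same unordered gene pair as cis pair c1, plus
  ## two fresh ones
  trans <- mk_calls(c("t1", "t2"), c("b", "x"), c("a", "y"),
                    matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                           dimnames = list(NULL, pats)))
  b <- trt_burden(cis, trans)
  expect_equal(b$cis, c(3L, 0L))
  expect_equal(b$trans, c(2L, 1L))
  ## p1 total: cis {ab, bc, cd} + trans {ab, xy} -> 4 unique events
  expect_equal(b$total, c(4L, 1L))
  ## all-false matrices give zeros
  cis0 <- mk_calls("c1", "a", "b",
                   matrix(FALSE, 1, 2, dimnames = list(NULL, pats)))
  expect_equal(trt_burden(cis0)$total, c(0L, 0L))
})

test_that("fold-change coupling correlation behaves on constructed pairs", {
  pats <- paste0("p", 1:5)
  pairs <- data.frame(pair_id = c("prA", "prB"),
                      upstream_gene = c("u1", "u2"),
                      downstream_gene = c("d1", "d2"))
  m <- rbind(
    prA = c(1, 2, 3, 4, 5), d1 = c(2, 4, 6, 8, 10),     # coupled
    prB = c(5, 4, 3, 2, 1), d2 = c(1, 2, 3, 4, 5),      # anti-coupled
    u1 = 1, u2 = 1, ctl = 1)
  colnames(m) <- pats
  em <- make_expr(m)
  baseline <- setNames(rep(1, nrow(m)), rownames(m))
  fc <- fc_correlation_per_pair(c("prA", "prB"), pairs, em, baseline, pats)
  expect_equal(fc$rho[fc$pair_id == "prA"], 1)
  expect_equal(fc$rho[fc$pair_id == "prB"], -1)
  ## six-point case against the rank oracle
  set.seed(2)
  pats6 <- paste0("q", 1:6)
  ig <- rlnorm(6); dn <- rlnorm(6)
  m6 <- rbind(prA = ig, d1 = dn, u1 = 1)
  colnames(m6) <- pats6
  fc6 <- fc_correlation_per_pair("prA", pairs[1, ], make_expr(m6),
                                 setNames(rep(1, 3), rownames(m6)), pats6)
  expect_equal(fc6$rho, spearman_rank_oracle(ig, dn))
  ## constant vectors are reported missing
  mc <- rbind(prA = rep(2, 5), d1 = 1:5, u1 = 1)
  colnames(mc) <- pats
  fcc <- fc_correlation_per_pair("prA", pairs[1, ], make_expr(mc),
                                 setNames(rep(1, 3), rownames(mc)), pats)
  expect_true(is.na(fcc$rho))
})

test_that("burden-trait battery runs the expected tests per class", {
  burden <- data.frame(patient_id = paste0("p", 1:8),
                       cis = c(5, 6, 7, 8, 1, 2, 3, 4),
                       trans = c(4, 3, 2, 1, 8, 7, 6, 5),
                       total = c(9, 9, 9, 9, 9, 9, 9, 13))
  clinical <- data.frame(sample_id = paste0("p", 1:8), group = "patient",
                         prognosis = rep(c("death", "remission"), each = 4),
                         virus = rep(c("yes", "no"), 4),
                         aki = "no",
                         neut_pct = c(90, 91, 92, 93, 80, 81, 82, 83))
  out <- burden_trait_tests(burden, clinical)
  expect_setequal(unique(out$class), c("cis", "trans", "total"))
  ## aki is single-level here: no test emitted for it
  expect_false("aki" %in% out$trait)
  cis_prog <- out[out$class == "cis" & out$trait == "prognosis", ]
  oracle <- compare_burden_groups(burden$cis, clinical$prognosis)
  expect_equal(cis_prog$p, oracle$p)
  cis_neut <- out[out$class == "cis" & out$trait == "neut_pct", ]
  expect_equal(cis_neut$estimate, spearman_rank_oracle(burden$cis, clinical$neut_pct))
})
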