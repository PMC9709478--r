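frag_df <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  data.frame(chrom = m[, 1], start = as.numeric(m[, 2]),
             end = as.numeric(m[, 3]), strand = m[, 4],
             stringsAsFactors = FALSE)
}

test_that("overlap counting is half-open with a 1 bp minimum", {
  fs <- fragment_set("s1", frag_df("chr1", 150, 250, "+",
                                   "chr1", 200, 300, "+"))
  iv <- list(chrom = "chr1", start = 100, end = 200, strand = "+")
  ## [150,250) overlaps, [200,300) abuts the half-open end and does not
  expect_equal(count_overlaps_interval(iv, fs), 1L)
  ## strand filter
  fs2 <- fragment_set("s1", frag_df("chr1", 150, 250, "-"))
  expect_equal(count_overlaps_interval(iv, fs2, stranded = TRUE), 0L)
  expect_equal(count_overlaps_interval(iv, fs2, stranded = FALSE), 1L)
})

test_that("overlap counts equal the naive all-pairs oracle on random instances", {
  set.seed(11)
  for (rep in 1:200) {
    nf <- sample(1:50, 1); ni <- sample(1:10, 1)
    frags <- data.frame(
      chrom = sample(c("c1", "c2"), nf, replace = TRUE),
      start = s <- sample(0:500, nf, replace = TRUE),
      end = s + sample(1:100, nf, replace = TRUE),
      strand = sample(c("+", "-"), nf, replace = TRUE))
    iv <- data.frame(
      chrom = sample(c("c1", "c2"), ni, replace = TRUE),
      start = s2 <- sample(0:500, ni, replace = TRUE),
      end = s2 + sample(1:150, ni, replace = TRUE),
      strand = sample(c("+", "-"), ni, replace = TRUE))
    fs <- fragment_set("s", frags)
    for (strd in c(TRUE, FALSE)) {
      got <- count_fragment_overlaps(iv, fs, stranded = strd)
      expect_equal(as.numeric(got), naive_overlap_count(iv, fs$fragments, strd))
    }
    ## unstranded counts dominate stranded counts
    expect_true(all(count_fragment_overlaps(iv, fs, FALSE) >=
                      count_fragment_overlaps(iv, fs, TRUE)))
  }
})

test_that("fpkm matches its closed form and rejects degenerate input", {
  expect_identical(fpkm(10, 1000, 1e6), 10)
  expect_identical(fpkm(0, 5000, 2e6), 0)
  expect_equal(fpkm(7, 2500, 3e6), 7 / (2.5 * 3))
  expect_error(fpkm(1, 0, 1e6), "length_bp")
  expect_error(fpkm(1, 100, 0), "library_size")
  expect_error(fpkm(-1, 100, 1e6), "count")
  ## monotone in count, decreasing in length
  expect_true(fpkm(11, 1000, 1e6) > fpkm(10, 1000, 1e6))
  expect_true(fpkm(10, 2000, 1e6) < fpkm(10, 1000, 1e6))
})

test_that("FPKM is invariant under uniform fragment duplication", {
  set.seed(3)
  cnt <- matrix(rpois(20, 30), 4, 5)
  lens <- c(500, 1000, 2000, 1500)
  lib <- colSums(cnt) + 100
  f1 <- fpkm(cnt, lens, rep(lib, each = 4))
  f2 <- fpkm(2 * cnt, lens, rep(2 * lib, each = 4))
  expect_equal(f1, f2)
})

test_that("quantify_features reproduces oracle counts through fpkm()", {
  genes <- gene_models(c("gA", "gB"), "chr1", c(100, 500), c(300, 800), c("+", "+"))
  pairs <- enumerate_adjacent_pairs(genes)
  frags <- frag_df(
    "chr1", 120, 280, "+",   # gA
    "chr1", 150, 350, "+",   # gA + intergenic
    "chr1", 310, 420, "+",   # intergenic
    "chr1", 320, 380, "-",   # intergenic, wrong strand
    "chr1", 510, 790, "+",   # gB
    "chr1", 450, 520, "+",   # intergenic + gB
    "chr1", 900, 950, "+",   # nothing
    "chr2", 100, 200, "+")   # unknown chrom
  fs <- fragment_set("s1", frags)
  expect_warning(em <- quantify_features(genes, pairs, list(fs), stranded = TRUE),
                 "chromosomes absent")
  feats <- data.frame(chrom = "chr1",
                      start = c(100, 500, 300), end = c(300, 800, 500),
                      strand = "+")
  oracle_counts <- naive_overlap_count(feats, frags, stranded = TRUE)
  oracle_fpkm <- fpkm(oracle_counts, c(200, 300, 200), nrow(frags))
  expect_equal(unname(em$fpkm[c("gA", "gB", pairs$pair_id), "s1"]), oracle_fpkm)
  expect_equal(unname(em$library_sizes), nrow(frags))
})

test_that("a sample with no overlapping fragments yields zero FPKM", {
  genes <- gene_models("g", "chr1", 0, 1000, "+")
  fs <- fragment_set("empty", frag_df("chr1", 5000, 5100, "+"))
  em <- quantify_features(genes, NULL, list(fs))
  expect_equal(unname(em$fpkm["g", ]), 0)
})

test_that("expression tables round-trip through TSV", {
  m <- matrix(c(1.5, 0, 2.25, 3), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  em <- make_expr(m, feature_type = c("gene", "intergenic"),
                  lib = c(s1 = 1e5, s2 = 2e5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(em, f)
  em2 <- load_expression_table(f)
  expect_equal(em2$fpkm, em$fpkm)
  expect_equal(em2$library_sizes, em$library_sizes)
  expect_equal(em2$feature_type, em$feature_type)
})

test_that("malformed expression tables are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "f1\t1.0\t-2.0"), f)
  expect_error(suppressWarnings(load_expression_table(f)), "negative")
  writeLines(c("feature_id\ts1\ts2", "f1\t1.0\tx"), f)
  expect_error(suppressWarnings(load_expression_table(f)), "non-numeric")
  writeLines(c("feature_id\ts1", "f1\t1.0"), f)
  expect_warning(em <- load_expression_table(f), "library size")
  expect_equal(unname(em$library_sizes), 1)
})

test_that("BAM fragments match their BED equivalent", {
  skip_if_not_installed("Rsamtools")
  ## two proper pairs (outer spans [100,250) and [300,500) on +/-) built
  ## as literal SAM text and converted to BAM
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    ## pair 1: + strand fragment, mates at 101..150 and 201..250 (1-based)
    "r1\t99\tchr1\t101\t60\t50M\t=\t201\t150\t*\t*",
    "r1\t147\tchr1\t201\t60\t50M\t=\t101\t-150\t*\t*",
    ## pair 2: - strand fragment (first mate reverse), 301..350 / 451..500
    "r2\t83\tchr1\t451\t60\t50M\t=\t301\t-200\t*\t*",
    "r2\t163\tchr1\t301\t60\t50M\t=\t451\t200\t*\t*")
  samf <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, samf)
  bamf <- Rsamtools::asBam(samf, withr::local_tempfile(), overwrite = TRUE)
  fs <- read_fragments_bam(bamf, "s1")
  got <- fs$fragments[order(fs$fragments$start), ]
  expect_equal(nrow(got), 2L)
  expect_equal(got$start, c(100, 300))
  expect_equal(got$end, c(250, 500))
  expect_equal(got$strand, c("+", "-"))
  expect_equal(fs$library_size, 2)
})
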