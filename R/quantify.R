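## Fragment coverage and FPKM quantification.
##
## A "fragment" is the outer span of a properly paired read pair (or a
## single read when unpaired). Overlap semantics follow coverage-tool
## defaults: a fragment counts toward a feature when they share >= 1 bp;
## under stranded counting the fragment strand must equal the feature
## strand. Intergenic intervals are counted on the upstream gene's strand.

#' Construct a fragment set
#'
#' @param sample_id sample identifier.
#' @param fragments data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`).
#' @param library_size total mapped fragments for the sample; defaults to
#'   `nrow(fragments)` (the retained-fragment count).
#' @return list of class `fragment_set`.
#' @export
fragment_set <- function(sample_id, fragments, library_size = nrow(fragments)) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end", "strand") %in% names(fragments)))
  if (nrow(fragments) && any(fragments$start >= fragments$end))
    .stopf("fragment intervals must satisfy start < end (sample %s)", sample_id)
  if (library_size < nrow(fragments))
    .stopf("library_size (%d) below stored fragment count (%d) for sample %s",
           library_size, nrow(fragments), sample_id)
  structure(list(sample_id = as.character(sample_id),
                 fragments = fragments,
                 library_size = as.numeric(library_size)),
            class = "fragment_set")
}

#' Read fragments from a BED6 file
#'
#' @param path BED file (0-based half-open; column 6 = strand).
#' @param sample_id sample identifier; defaults to the file stem.
#' @return a [fragment_set()].
#' @export
read_fragments_bed <- function(path, sample_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) .stopf("fragment BED not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 6L) .stopf("fragment BED must have >= 6 columns: %s", path)
  fr <- data.frame(chrom = as.character(raw[[1]]), start = as.numeric(raw[[2]]),
                   end = as.numeric(raw[[3]]), strand = as.character(raw[[6]]),
                   stringsAsFactors = FALSE)
  fragment_set(sample_id, fr)
}

#' Read fragments from a coordinate-sorted BAM
#'
#' Properly paired reads are collapsed to their outer fragment span;
#' remaining single-end alignments count as one fragment each. For a
#' strand-specific dUTP-style library the fragment strand is taken from
#' the first mate.
#'
#' @param path indexed BAM file.
#' @param sample_id sample identifier.
#' @param min_mapq drop alignments below this mapping quality.
#' @return a [fragment_set()].
#' @export
read_fragments_bam <- function(path, sample_id = tools::file_path_sans_ext(basename(path)),
                               min_mapq = 0) {
  if (!file.exists(path)) .stopf("BAM not found: %s", path)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = min_mapq)
  pairs <- GenomicAlignments::readGAlignmentPairs(path, param = param)
  pr <- GenomicRanges::granges(pairs)  # outer span, strand of first mate
  singles <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isPaired = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE),
      mapqFilter = min_mapq))
  sr <- GenomicRanges::granges(singles)
  all <- c(pr, sr)
  fr <- data.frame(chrom = as.character(GenomicRanges::seqnames(all)),
                   start = BiocGenerics::start(all) - 1L,
                   end = BiocGenerics::end(all),
                   strand = as.character(BiocGenerics::strand(all)),
                   stringsAsFactors = FALSE)
  fragment_set(sample_id, fr)
}

.features_to_gr <- function(chrom, start, end, strand, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- unique(chrom)
  GenomicRanges::GRanges(factor(chrom, levels = seqlevels),
                         IRanges::IRanges(start = start + 1, end = end),
                         strand = strand)
}

#' Count fragments overlapping features
#'
#' Vectorized >=1 bp overlap counting; with `stranded = TRUE` only
#' fragments on the feature's strand are counted.
#'
#' @param features data frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param frags a [fragment_set()].
#' @param stranded logical; strand-specific counting (default `TRUE`).
#' @return integer vector of counts, one per feature row.
#' @export
count_fragment_overlaps <- function(features, frags, stranded = TRUE) {
  stopifnot(inherits(frags, "fragment_set"))
  if (nrow(features) == 0L) return(integer())
  if (nrow(frags$fragments) == 0L) return(integer(nrow(features)))
  lev <- unique(c(features$chrom, frags$fragments$chrom))
  fgr <- .features_to_gr(features$chrom, features$start, features$end,
                         features$strand, seqlevels = lev)
  rgr <- .features_to_gr(frags$fragments$chrom, frags$fragments$start,
                         frags$fragments$end, frags$fragments$strand,
                         seqlevels = lev)
  GenomicRanges::countOverlaps(fgr, rgr, minoverlap = 1L,
                               ignore.strand = !stranded)
}

#' Count fragments overlapping a single interval
#'
#' @param interval list or one-row data frame with `chrom`, `start`,
#'   `end`, `strand`.
#' @inheritParams count_fragment_overlaps
#' @return a single non-negative integer.
#' @export
count_overlaps_interval <- function(interval, frags, stranded = TRUE) {
  f <- data.frame(chrom = interval$chrom, start = interval$start,
                  end = interval$end, strand = interval$strand,
                  stringsAsFactors = FALSE)
  count_fragment_overlaps(f, frags, stranded = stranded)[1L]
}

#' Fragments per kilobase per million mapped fragments
#'
#' `count / ((length_bp/1000) * (library_size/1e6))`.
#'
#' @param count non-negative fragment count (vectorized).
#' @param length_bp feature length in bp (> 0).
#' @param library_size total mapped fragments in the sample (> 0).
#' @return non-negative FPKM value(s).
#' @export
fpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) .stopf("length_bp must be positive")
  if (any(library_size <= 0)) .stopf("library_size must be positive")
  if (any(count < 0)) .stopf("count must be non-negative")
  count / ((length_bp / 1000) * (library_size / 1e6))
}

#' Construct an expression matrix container
#'
#' Holds FPKM per feature (gene or pair intergenic interval) per sample
#' together with per-sample library sizes. Absent coverage is 0, never
#' missing.
#'
#' @param fpkm numeric feature x sample matrix with dimnames.
#' @param library_sizes named per-sample library sizes.
#' @param feature_type optional character vector (`"gene"` or
#'   `"intergenic"`) aligned with rows.
#' @param counts optional raw count matrix with identical dimensions.
#' @return object of class `trt_expr`.
#' @export
expression_matrix <- function(fpkm, library_sizes,
                              feature_type = NULL, counts = NULL) {
  stopifnot(is.matrix(fpkm), !is.null(rownames(fpkm)), !is.null(colnames(fpkm)))
  if (any(is.na(fpkm)) || any(fpkm < 0))
    .stopf("FPKM values must be non-negative and non-missing")
  if (is.null(names(library_sizes))) names(library_sizes) <- colnames(fpkm)
  if (!setequal(names(library_sizes), colnames(fpkm)) ||
      length(library_sizes) != ncol(fpkm))
    .stopf("library_sizes names must match sample ids")
  if (any(library_sizes <= 0)) .stopf("library sizes must be positive")
  if (is.null(feature_type))
    feature_type <- rep("gene", nrow(fpkm))
  structure(list(fpkm = fpkm,
                 feature_ids = rownames(fpkm),
                 sample_ids = colnames(fpkm),
                 library_sizes = library_sizes[colnames(fpkm)],
                 feature_type = feature_type,
                 counts = counts),
            class = "trt_expr")
}

#' @export
print.trt_expr <- function(x, ...) {
  cat(sprintf("<trt_expr> %d features x %d samples (%d gene, %d intergenic)\n",
              nrow(x$fpkm), ncol(x$fpkm),
              sum(x$feature_type == "gene"),
              sum(x$feature_type == "intergenic")))
  invisible(x)
}

#' Quantify genes and intergenic intervals across samples
#'
#' Counts fragments over every gene body and every pair's intergenic
#' interval, then converts to FPKM with each sample's library size.
#' Intergenic intervals are counted on the upstream gene's strand when
#' `stranded`.
#'
#' @param genes a [gene_models()] table.
#' @param pairs pair table from [enumerate_adjacent_pairs()] (may be
#'   `NULL` to quantify genes only).
#' @param samples list of [fragment_set()] objects.
#' @param stranded strand-specific counting flag.
#' @return a [expression_matrix()] (`trt_expr`); rows are gene ids
#'   followed by pair ids.
#' @export
quantify_features <- function(genes, pairs = NULL, samples, stranded = TRUE) {
  if (!length(samples)) .stopf("no samples supplied")
  feats <- data.frame(feature_id = genes$gene_id, chrom = genes$chrom,
                      start = genes$start, end = genes$end,
                      strand = genes$strand,
                      type = "gene", stringsAsFactors = FALSE)
  if (!is.null(pairs) && nrow(pairs)) {
    feats <- rbind(feats, data.frame(
      feature_id = pairs$pair_id, chrom = pairs$chrom,
      start = pairs$intergenic_start, end = pairs$intergenic_end,
      strand = pairs$upstream_strand, type = "intergenic",
      stringsAsFactors = FALSE))
  }
  known_chroms <- unique(feats$chrom)
  cnt <- matrix(0L, nrow = nrow(feats), ncol = length(samples),
                dimnames = list(feats$feature_id,
                                unname(vapply(samples, `[[`, "", "sample_id"))))
  lib <- numeric(length(samples))
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    if (s$library_size <= 0)
      .stopf("sample '%s' has zero library size", s$sample_id)
    stray <- setdiff(unique(s$fragments$chrom), known_chroms)
    if (length(stray))
      .warnf("sample '%s': ignoring fragments on chromosomes absent from the annotation: %s",
             s$sample_id, paste(stray, collapse = ", "))
    cnt[, j] <- count_fragment_overlaps(feats, s, stranded = stranded)
    lib[j] <- s$library_size
  }
  names(lib) <- colnames(cnt)
  fp <- sweep(cnt / (feats$end - feats$start) * 1000, 2, lib / 1e6, "/")
  expression_matrix(fp, lib, feature_type = feats$type, counts = cnt)
}

#' Write an expression matrix and its library-size sidecar
#'
#' @param expr a `trt_expr` object.
#' @param path TSV output path (first column `feature_id`, then samples).
#' @param libsize_path sidecar TSV (`sample_id`, `library_size`); default
#'   `<path>.libsize`.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path,
                                   libsize_path = paste0(path, ".libsize")) {
  stopifnot(inherits(expr, "trt_expr"))
  df <- data.frame(feature_id = expr$feature_ids,
                   feature_type = expr$feature_type,
                   expr$fpkm, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(df, path)
  write_tsv_table(data.frame(sample_id = names(expr$library_sizes),
                             library_size = as.numeric(expr$library_sizes)),
                  libsize_path)
  invisible(path)
}

#' Load an expression matrix from TSV
#'
#' Expects the layout written by [write_expression_table()] (or any TSV
#' with feature ids in the first column and one column per sample). When
#' the library-size sidecar is absent, all library sizes are set to 1
#' with a warning; fold-change-based screen steps are unaffected because
#' they consume FPKM ratios.
#'
#' @param path TSV path.
#' @param libsize_path sidecar path (default `<path>.libsize`).
#' @return a `trt_expr` object.
#' @export
load_expression_table <- function(path, libsize_path = paste0(path, ".libsize")) {
  df <- read_tsv_table(path)
  if (ncol(df) < 2L) .stopf("expression table needs a feature column plus samples")
  ft <- NULL
  if ("feature_type" %in% names(df)) {
    ft <- df$feature_type
    df <- df[setdiff(names(df), "feature_type")]
  }
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) .stopf("non-numeric values in expression table %s", path)
  if (any(is.na(m))) .stopf("missing values in expression table %s", path)
  if (any(m < 0)) .stopf("negative FPKM values in expression table %s", path)
  rownames(m) <- as.character(df[[1L]])
  if (file.exists(libsize_path)) {
    ls <- read_tsv_table(libsize_path)
    lib <- stats::setNames(as.numeric(ls$library_size), ls$sample_id)
    if (!all(colnames(m) %in% names(lib)))
      .stopf("library-size sidecar misses samples: %s",
             paste(setdiff(colnames(m), names(lib)), collapse = ", "))
    lib <- lib[colnames(m)]
  } else {
    .warnf("no library-size sidecar at %s; setting library sizes to 1", libsize_path)
    lib <- stats::setNames(rep(1, ncol(m)), colnames(m))
  }
  expression_matrix(m, lib, feature_type = ft)
}
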