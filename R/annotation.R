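## Gene-model input and adjacent-pair enumeration.
##
## Coordinates are 0-based half-open everywhere inside the package;
## 1-based inclusive GTF/GFF coordinates are converted at the I/O
## boundary (BED is already 0-based half-open).

#' Construct a gene-model table
#'
#' The gene model is the unit of pair enumeration: one row per gene with
#' its genomic span and strand. Internal coordinates are 0-based
#' half-open, so `length_bp = end - start`.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open span (start < end).
#' @param strand `"+"` or `"-"`.
#' @param biotype optional biotype labels (e.g. `"protein_coding"`,
#'   `"lncRNA"`); defaults to `NA`.
#' @return data frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `length_bp`, `biotype`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand, biotype = NA_character_) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    .stopf("duplicate gene_id: %s",
           paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start >= end))
    .stopf("gene coordinates must satisfy start < end")
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    .stopf("strand must be '+' or '-'")
  out <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    start = start, end = end, strand = strand,
                    length_bp = end - start,
                    biotype = rep_len(as.character(biotype), length(gene_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Read gene models from an annotation file
#'
#' Supports Ensembl-dialect GTF (attribute key `gene_id`), GFF3 (attribute
#' `ID` or `gene_id`), and BED12/BED6. Only `gene`-type records are used
#' from GTF/GFF3; if none are present, distinct `gene_id` spans are built
#' from the remaining records. GTF/GFF 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention.
#'
#' @param path annotation file path.
#' @param format one of `"auto"`, `"gtf"`, `"gff3"`, `"bed12"`.
#' @return a [gene_models()] table.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "gff3", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     bed = "bed12", bed12 = "bed12",
                     .stopf("cannot infer annotation format from '%s'", path))
  }
  content <- readLines(path, warn = FALSE)
  if (!length(grep("^[^#[:space:]]", content)))
    return(gene_models(character(), character(), numeric(), numeric(), character()))
  if (format %in% c("gtf", "gff3")) {
    gr <- tryCatch(
      rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3"),
      error = function(e) .stopf("failed to parse %s as %s: %s",
                                 path, format, conditionMessage(e)))
    if (length(gr) == 0L)
      return(gene_models(character(), character(), numeric(), numeric(), character()))
    md <- S4Vectors::mcols(gr)
    is_gene <- !is.null(md$type) & as.character(md$type) == "gene"
    if (any(is_gene)) gr <- gr[is_gene]
    ids <- if (!is.null(S4Vectors::mcols(gr)$gene_id)) {
      as.character(S4Vectors::mcols(gr)$gene_id)
    } else if (!is.null(S4Vectors::mcols(gr)$ID)) {
      as.character(S4Vectors::mcols(gr)$ID)
    } else .stopf("no gene_id/ID attribute found in %s", path)
    if (anyNA(ids)) .stopf("records without gene_id in %s", path)
    bt <- S4Vectors::mcols(gr)$gene_biotype
    if (is.null(bt)) bt <- S4Vectors::mcols(gr)$biotype
    if (is.null(bt)) bt <- NA_character_
    st <- as.character(BiocGenerics::strand(gr))
    if (any(st == "*")) .stopf("unstranded gene records in %s", path)
    ## GTF/GFF 1-based inclusive -> 0-based half-open
    gene_models(ids, as.character(GenomicRanges::seqnames(gr)),
                BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                st, as.character(bt))
  } else {
    bed <- tryCatch(rtracklayer::import(path, format = "bed"),
                    error = function(e) .stopf("failed to parse %s as BED: %s",
                                               path, conditionMessage(e)))
    if (length(bed) == 0L)
      return(gene_models(character(), character(), numeric(), numeric(), character()))
    ids <- S4Vectors::mcols(bed)$name
    if (is.null(ids) || anyNA(ids)) .stopf("BED records need a name field (gene id)")
    st <- as.character(BiocGenerics::strand(bed))
    if (any(st == "*")) .stopf("BED gene records must carry a strand")
    gene_models(as.character(ids), as.character(GenomicRanges::seqnames(bed)),
                BiocGenerics::start(bed) - 1L, BiocGenerics::end(bed), st)
  }
}

#' Enumerate adjacent gene pairs with intergenic intervals
#'
#' Per chromosome, genes are sorted by start and each consecutive
#' non-overlapping pair of gene bodies defines a gap. A gene is eligible
#' as "upstream" only when its 3' end (the transcription termination
#' site) borders the gap: a `+` gene on the left of the gap or a `-`
#' gene on its right. Same-strand neighbours therefore yield exactly one
#' cis pair; convergent opposite-strand neighbours yield two directed
#' trans pairs (read-through can enter the gap from either side);
#' divergent neighbours yield none.
#'
#' @param genes a [gene_models()] table.
#' @param min_intergenic_bp,max_intergenic_bp keep pairs whose intergenic
#'   length is within `[min, max]`.
#' @return data frame with one row per directed pair: `pair_id`,
#'   `upstream_gene`, `downstream_gene`, `chrom`, `pair_class`
#'   (`"cis"`/`"trans"`), `upstream_strand`, `intergenic_start`,
#'   `intergenic_end`, `intergenic_length`.
#' @export
enumerate_adjacent_pairs <- function(genes, min_intergenic_bp = 1,
                                     max_intergenic_bp = Inf) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 0)
  .assert_scalar_num(min_intergenic_bp, "min_intergenic_bp", lower = 1)
  .assert_scalar_num(max_intergenic_bp, "max_intergenic_bp", lower = min_intergenic_bp)
  empty <- data.frame(pair_id = character(), upstream_gene = character(),
                      downstream_gene = character(), chrom = character(),
                      pair_class = character(), upstream_strand = character(),
                      intergenic_start = numeric(), intergenic_end = numeric(),
                      intergenic_length = numeric(), stringsAsFactors = FALSE)
  if (nrow(genes) < 2L) return(empty)
  genes <- genes[order(genes$chrom, genes$start, genes$end, genes$gene_id), ]
  rows <- vector("list", nrow(genes))
  k <- 0L
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, ]
    if (nrow(g) < 2L) next
    for (i in seq_len(nrow(g) - 1L)) {
      left <- g[i, ]; right <- g[i + 1L, ]
      gap_start <- left$end; gap_end <- right$start
      len <- gap_end - gap_start
      if (len < min_intergenic_bp || len > max_intergenic_bp) next  # overlap => len <= 0
      left_up  <- left$strand == "+"   # TTS of left gene borders gap
      right_up <- right$strand == "-"  # TTS of right gene borders gap
      cls <- if (left$strand == right$strand) "cis" else "trans"
      if (left_up) {
        k <- k + 1L
        rows[[k]] <- data.frame(upstream_gene = left$gene_id,
                                downstream_gene = right$gene_id, chrom = chr,
                                pair_class = cls, upstream_strand = left$strand,
                                intergenic_start = gap_start,
                                intergenic_end = gap_end,
                                intergenic_length = len, stringsAsFactors = FALSE)
      }
      if (right_up) {
        k <- k + 1L
        rows[[k]] <- data.frame(upstream_gene = right$gene_id,
                                downstream_gene = left$gene_id, chrom = chr,
                                pair_class = cls, upstream_strand = right$strand,
                                intergenic_start = gap_start,
                                intergenic_end = gap_end,
                                intergenic_length = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(k)])
  out <- cbind(pair_id = paste0("pair_", out$upstream_gene, "_", out$downstream_gene),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export intergenic intervals as BED6
#'
#' One record per pair: name is the pair id, strand is the upstream
#' gene's strand (the strand read-through fragments are expected on).
#'
#' @param pairs pair table from [enumerate_adjacent_pairs()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_intergenic_bed <- function(pairs, path) {
  bed <- data.frame(pairs$chrom, format(pairs$intergenic_start, scientific = FALSE, trim = TRUE),
                    format(pairs$intergenic_end, scientific = FALSE, trim = TRUE),
                    pairs$pair_id, 0L, pairs$upstream_strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
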