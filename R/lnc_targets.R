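## cis/trans target prediction for differentially expressed lncRNAs.
##
## cis: protein-coding genes within a fixed genomic window (default
## 50 kb) of the lncRNA span on the same chromosome, strand ignored.
## trans: co-expression (|Spearman R| > 0.9, p < 0.05, both strict),
## optionally intersected with a lncRNA-gene binding-evidence table
## (e.g. triplex-prediction output consumed as TSV).

#' cis target genes by genomic proximity
#'
#' For each lncRNA, every coding gene on the same chromosome whose body
#' overlaps the lncRNA span extended by `window_bp` on each side.
#' `distance_bp` is the signed gap between nearest edges: 0 when the
#' bodies overlap, negative when the coding gene lies on the lower-
#' coordinate side of the lncRNA.
#'
#' @param lncs,coding [gene_models()] tables.
#' @param window_bp window half-width in bp (default 50000).
#' @return data frame `lnc_id`, `target_gene_id`, `mode` (`"cis"`),
#'   `distance_bp`.
#' @export
cis_targets <- function(lncs, coding, window_bp = 50000) {
  stopifnot(nrow(lncs) > 0, nrow(coding) > 0)
  .assert_scalar_num(window_bp, "window_bp", lower = 0)
  ## extend by window + 1 so that a gap of exactly window_bp still
  ## overlaps under half-open interval semantics (|distance| <= window)
  lev <- unique(c(lncs$chrom, coding$chrom))
  lg <- .features_to_gr(lncs$chrom, pmax(0, lncs$start - window_bp - 1),
                        lncs$end + window_bp + 1, "*", seqlevels = lev)
  cg <- .features_to_gr(coding$chrom, coding$start, coding$end, "*",
                        seqlevels = lev)
  hits <- GenomicRanges::findOverlaps(lg, cg, minoverlap = 1L,
                                      ignore.strand = TRUE)
  li <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
  if (!length(li))
    return(data.frame(lnc_id = character(), target_gene_id = character(),
                      mode = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE))
  gap <- ifelse(coding$end[ci] <= lncs$start[li],
                coding$end[ci] - lncs$start[li],          # negative: below lnc
                ifelse(coding$start[ci] >= lncs$end[li],
                       coding$start[ci] - lncs$end[li],   # positive: above lnc
                       0))
  data.frame(lnc_id = lncs$gene_id[li],
             target_gene_id = coding$gene_id[ci],
             mode = "cis", distance_bp = as.numeric(gap),
             stringsAsFactors = FALSE)
}

#' trans target genes by co-expression
#'
#' All lncRNA x coding-gene pairs with |Spearman R| strictly above
#' `r_min` and p strictly below `p_max` across shared samples.
#'
#' @param lnc_expr,coding_expr numeric feature x sample matrices (or
#'   `trt_expr` objects) sharing >= 3 sample ids.
#' @param r_min correlation magnitude threshold (default 0.9, strict).
#' @param p_max p-value threshold (default 0.05, strict).
#' @return data frame `lnc_id`, `target_gene_id`, `mode` (`"trans"`),
#'   `coexpression_R`, `p`, `binding_supported` (all `FALSE` until
#'   [intersect_binding()]).
#' @export
trans_coexpression_targets <- function(lnc_expr, coding_expr,
                                       r_min = 0.9, p_max = 0.05) {
  as_mat <- function(x) if (inherits(x, "trt_expr")) x$fpkm else as.matrix(x)
  lm <- as_mat(lnc_expr); cm <- as_mat(coding_expr)
  shared <- intersect(colnames(lm), colnames(cm))
  if (length(shared) < 3L) .stopf("fewer than 3 shared samples")
  lm <- lm[, shared, drop = FALSE]; cm <- cm[, shared, drop = FALSE]
  ## rank-transform once; Pearson on ranks = Spearman rho
  rl <- t(apply(lm, 1, rank)); rc <- t(apply(cm, 1, rank))
  suppressWarnings(rho <- stats::cor(t(rl), t(rc)))
  rho[is.na(rho)] <- 0  # constant features cannot qualify
  cand <- which(abs(rho) > r_min, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(lnc_id = character(), target_gene_id = character(),
                      mode = character(), coexpression_R = numeric(),
                      p = numeric(), binding_supported = logical()))
  res <- lapply(seq_len(nrow(cand)), function(k) {
    i <- cand[k, 1]; j <- cand[k, 2]
    s <- .spearman(lm[i, ], cm[j, ])
    data.frame(lnc_id = rownames(lm)[i], target_gene_id = rownames(cm)[j],
               mode = "trans", coexpression_R = s$rho, p = s$p,
               binding_supported = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  keep <- !is.na(out$coexpression_R) & abs(out$coexpression_R) > r_min &
    !is.na(out$p) & out$p < p_max
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect trans predictions with binding evidence
#'
#' Keeps trans predictions whose (lncRNA, gene) pair appears in a
#' binding-evidence table (TSV columns `lnc_id`, `gene_id`), flagging
#' them `binding_supported`. With `strict = FALSE`, unsupported
#' predictions pass through unflagged. With no table at all, everything
#' passes through with a warning.
#'
#' @param predictions output of [trans_coexpression_targets()].
#' @param binding_table data frame with `lnc_id`, `gene_id`, or a TSV
#'   path; `NULL` for no evidence.
#' @param strict drop unsupported predictions (default `TRUE`, binding
#'   AND co-expression as joint criteria).
#' @return filtered predictions with `binding_supported` set.
#' @export
intersect_binding <- function(predictions, binding_table = NULL, strict = TRUE) {
  if (is.null(binding_table)) {
    .warnf("no binding table supplied; passing all trans predictions through unsupported")
    predictions$binding_supported <- FALSE
    return(predictions)
  }
  if (is.character(binding_table)) binding_table <- read_tsv_table(binding_table)
  if (!all(c("lnc_id", "gene_id") %in% names(binding_table)))
    .stopf("binding table needs columns lnc_id and gene_id")
  n_unknown <- sum(!(binding_table$lnc_id %in% predictions$lnc_id))
  if (n_unknown && nrow(predictions))
    message(sprintf("binding table: %d rows reference lncRNAs absent from the predictions (ignored)",
                    n_unknown))
  bkey <- paste(binding_table$lnc_id, binding_table$gene_id, sep = "\t")
  pkey <- paste(predictions$lnc_id, predictions$target_gene_id, sep = "\t")
  predictions$binding_supported <- pkey %in% bkey
  if (strict)
    predictions <- predictions[predictions$binding_supported, , drop = FALSE]
  rownames(predictions) <- NULL
  predictions
}
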