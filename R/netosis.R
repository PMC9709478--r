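## Gene-set activity scoring by PCA.
##
## The score is principal component 1 of the expression of a gene set
## (here NETosis pathway genes) restricted to genes expressed in more
## than half of the patients. The PC1 sign is arbitrary; it is oriented
## so that the majority of per-gene correlations with PC1 are negative,
## the convention under which a LOWER score means HIGHER gene-set
## activity.

#' Select gene-set genes expressed in enough patients
#'
#' Keeps genes with FPKM strictly above `min_fpkm` in strictly more than
#' `min_frac` of the patients. Gene-set members absent from the matrix
#' are ignored with a warning.
#'
#' @param expr a `trt_expr` object.
#' @param gene_set character vector of gene ids.
#' @param patient_ids patient sample ids.
#' @param min_frac expression-prevalence threshold (default 0.5).
#' @param min_fpkm FPKM above which a gene counts as expressed
#'   (default 0).
#' @return character vector of surviving gene ids.
#' @export
select_expressed_genes <- function(expr, gene_set, patient_ids,
                                   min_frac = 0.5, min_fpkm = 0) {
  stopifnot(inherits(expr, "trt_expr"), length(gene_set) > 0)
  miss <- setdiff(gene_set, expr$feature_ids)
  if (length(miss)) {
    .warnf("%d gene-set genes absent from the expression matrix (ignored)",
           length(miss))
    gene_set <- setdiff(gene_set, miss)
  }
  if (!length(gene_set)) .stopf("no gene-set genes present in the expression matrix")
  m <- expr$fpkm[gene_set, patient_ids, drop = FALSE]
  frac <- rowMeans(m > min_fpkm)
  keep <- gene_set[frac > min_frac]
  if (!length(keep))
    .stopf("no gene-set genes expressed in > %.0f%% of patients; lower min_frac or min_fpkm",
           100 * min_frac)
  keep
}

#' PC1 gene-set score
#'
#' Principal component 1 of the genes x samples submatrix after the
#' chosen per-gene scaling. Default `"zscore"` (centre and scale each
#' gene) because FPKM spans orders of magnitude and unscaled PCA would
#' be dominated by the most highly expressed genes.
#'
#' @param expr a `trt_expr` object.
#' @param genes selected gene ids (>= 2).
#' @param sample_ids samples to score (>= 3).
#' @param scaling `"zscore"`, `"center"`, or `"none"`.
#' @return object of class `geneset_score`: list with `scores` (named
#'   per-sample PC1), `loadings` (named per-gene, unit norm),
#'   `variance_explained`, `scaling`, plus orientation diagnostics
#'   filled by [orient_and_diagnose()].
#' @export
pc1_score <- function(expr, genes, sample_ids,
                      scaling = c("zscore", "center", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(expr, "trt_expr"))
  if (length(genes) < 2L) .stopf("need >= 2 genes for PCA")
  if (length(sample_ids) < 3L) .stopf("need >= 3 samples for PCA")
  m <- t(expr$fpkm[genes, sample_ids, drop = FALSE])  # samples x genes
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) .stopf("zero-variance expression matrix")
  if (scaling == "zscore" && any(sds == 0))
    .stopf("zero-variance genes prevent z-scoring: %s",
           paste(utils::head(genes[sds == 0], 5), collapse = ", "))
  pc <- stats::prcomp(m, center = scaling != "none",
                      scale. = scaling == "zscore")
  ve <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  structure(list(scores = stats::setNames(pc$x[, 1L], sample_ids),
                 loadings = stats::setNames(pc$rotation[, 1L], genes),
                 variance_explained = ve,
                 scaling = scaling,
                 gene_cor = NULL, n_negative = NA_integer_,
                 n_total = length(genes), oriented = FALSE),
            class = "geneset_score")
}

#' @export
print.geneset_score <- function(x, ...) {
  cat(sprintf("<geneset_score> %d genes, %d samples; PC1 explains %.1f%% of variance%s\n",
              x$n_total, length(x$scores), 100 * x$variance_explained,
              if (x$oriented)
                sprintf("; %d/%d genes negatively correlated with PC1",
                        x$n_negative, x$n_total) else " (unoriented)"))
  invisible(x)
}

#' Orient PC1 and fill correlation diagnostics
#'
#' Computes each gene's Spearman correlation with PC1 and flips the sign
#' of the score (and loadings) so that the majority of gene correlations
#' are negative; under this convention lower PC1 means higher gene-set
#' expression. On an exact 50/50 split the component is flipped when the
#' sum of correlations is positive. Orientation never changes any |R|.
#'
#' @param score a [pc1_score()] result.
#' @param expr the `trt_expr` the score was computed from.
#' @return the `geneset_score` with `scores`/`loadings` oriented and
#'   `gene_cor`, `n_negative`, `n_total` filled.
#' @export
orient_and_diagnose <- function(score, expr) {
  stopifnot(inherits(score, "geneset_score"), inherits(expr, "trt_expr"))
  genes <- names(score$loadings)
  samples <- names(score$scores)
  cors <- vapply(genes, function(g) {
    suppressWarnings(stats::cor(expr$fpkm[g, samples], score$scores,
                                method = "spearman"))
  }, numeric(1))
  n_neg <- sum(cors < 0, na.rm = TRUE)
  n_pos <- sum(cors > 0, na.rm = TRUE)
  flip <- n_neg < n_pos || (n_neg == n_pos && sum(cors, na.rm = TRUE) > 0)
  if (flip) {
    score$scores <- -score$scores
    score$loadings <- -score$loadings
    cors <- -cors
  }
  score$gene_cor <- cors
  score$n_negative <- sum(cors < 0, na.rm = TRUE)
  score$n_total <- length(genes)
  score$oriented <- TRUE
  score
}

#' Associate the gene-set score with clinical traits
#'
#' Wilcoxon rank-sum for binary traits (virus, aki, prognosis) and
#' Spearman correlation for numeric traits, over the scored samples.
#'
#' @param score an oriented `geneset_score`.
#' @param clinical table from [read_clinical_table()].
#' @param binary_traits,numeric_traits trait columns to test (present
#'   columns only).
#' @return data frame `trait`, `test`, `statistic`, `estimate`, `p`, `n`.
#' @export
associate_score_traits <- function(score, clinical,
                                   binary_traits = c("virus", "aki", "prognosis"),
                                   numeric_traits = c("paco2", "pao2_fio2",
                                                      "age", "neut_pct")) {
  stopifnot(inherits(score, "geneset_score"))
  cl <- clinical[match(names(score$scores), clinical$sample_id), , drop = FALSE]
  if (anyNA(cl$sample_id)) .stopf("scored samples missing from the clinical table")
  v <- as.numeric(score$scores)
  out <- list()
  for (tr in intersect(binary_traits, names(cl))) {
    lab <- cl[[tr]]; ok <- !is.na(lab)
    if (length(unique(lab[ok])) != 2L || sum(ok) < 3L) next
    w <- compare_burden_groups(v[ok], lab[ok])
    out[[length(out) + 1L]] <- data.frame(
      trait = tr, test = "wilcoxon", statistic = w$statistic,
      estimate = NA_real_, p = w$p, n = sum(ok), stringsAsFactors = FALSE)
  }
  for (tr in intersect(numeric_traits, names(cl))) {
    x <- as.numeric(cl[[tr]])
    ok <- is.finite(x)
    s <- if (sum(ok) < 3L) list(rho = NA_real_, p = NA_real_, n = sum(ok))
         else .spearman(v, x)
    out[[length(out) + 1L]] <- data.frame(
      trait = tr, test = "spearman", statistic = NA_real_,
      estimate = s$rho, p = s$p, n = s$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-gene correlation scan against a numeric trait
#'
#' Spearman correlation between each gene-set gene's FPKM and the trait
#' (e.g. PaO2/FiO2), sorted by p-value. Constant genes are reported with
#' missing correlation.
#'
#' @param expr a `trt_expr` object.
#' @param gene_set gene ids to scan (absent genes ignored with warning).
#' @param trait named or aligned numeric trait over `sample_ids`.
#' @param sample_ids samples to use (default: all in `expr`).
#' @return data frame `gene_id`, `rho`, `p`, `n` sorted by `p`.
#' @export
gene_trait_correlation_scan <- function(expr, gene_set, trait,
                                        sample_ids = expr$sample_ids) {
  miss <- setdiff(gene_set, expr$feature_ids)
  if (length(miss)) {
    .warnf("%d scan genes absent from the expression matrix (ignored)", length(miss))
    gene_set <- setdiff(gene_set, miss)
  }
  trait <- as.numeric(trait)
  if (length(trait) != length(sample_ids))
    .stopf("trait length must match sample_ids")
  res <- lapply(gene_set, function(g) {
    x <- expr$fpkm[g, sample_ids]
    ok <- is.finite(trait)
    if (sum(ok) < 3L)
      return(data.frame(gene_id = g, rho = NA_real_, p = NA_real_, n = sum(ok)))
    if (stats::sd(x[ok]) == 0)
      return(data.frame(gene_id = g, rho = NA_real_, p = NA_real_, n = sum(ok)))
    s <- .spearman(x, trait)
    data.frame(gene_id = g, rho = s$rho, p = s$p, n = s$n)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
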