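## Downstream statistics on screen output: intergenic/downstream
## fold-change coupling, per-patient burden, and clinical-trait tests
## (Wilcoxon rank-sum, Spearman correlation, chi-square), all reported
## as raw p-values.

.spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    .stopf("fewer than 3 complete observation pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = !ties))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-pair correlation between intergenic and downstream fold change
#'
#' For each selected pair, Spearman's correlation across patients between
#' the intergenic fold change and the downstream-gene fold change over
#' the control baseline. When a control mean is zero the patient FPKM is
#' used in place of the undefined ratio; ranks, and hence the
#' correlation, are unaffected because the per-pair denominator is
#' constant across patients.
#'
#' @param pair_ids pairs to evaluate (e.g. [recurrent_pairs()] output).
#' @param pairs full pair table (maps pair ids to downstream genes).
#' @param expr a `trt_expr` object.
#' @param baseline [control_baseline()] vector.
#' @param patient_ids patient sample ids (>= 3).
#' @return data frame `pair_id`, `rho`, `p`, `n`; constant fold-change
#'   vectors yield missing `rho`.
#' @export
fc_correlation_per_pair <- function(pair_ids, pairs, expr, baseline, patient_ids) {
  if (length(patient_ids) < 3L) .stopf("need >= 3 patients")
  idx <- match(pair_ids, pairs$pair_id)
  if (anyNA(idx)) .stopf("unknown pair ids")
  res <- lapply(seq_along(pair_ids), function(k) {
    pid <- pair_ids[k]
    dn_gene <- pairs$downstream_gene[idx[k]]
    ig <- expr$fpkm[pid, patient_ids]
    dn <- expr$fpkm[dn_gene, patient_ids]
    bi <- baseline[[pid]]; bd <- baseline[[dn_gene]]
    fc_ig <- if (bi > 0) ig / bi else ig
    fc_dn <- if (bd > 0) dn / bd else dn
    if (stats::sd(fc_ig) == 0 || stats::sd(fc_dn) == 0)
      return(data.frame(pair_id = pid, rho = NA_real_, p = NA_real_,
                        n = length(patient_ids)))
    s <- .spearman(fc_ig, fc_dn)
    data.frame(pair_id = pid, rho = s$rho, p = s$p, n = s$n)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(pair_id = character(), rho = numeric(),
                      p = numeric(), n = integer())
  rownames(out) <- NULL
  out
}

#' Per-patient read-through burden
#'
#' Counts positive pairs per patient for the cis and trans call matrices
#' and their union. For the union, directed pairs over the same unordered
#' gene pair (the two directions of a convergent trans pair) count once.
#'
#' @param cis_calls,trans_calls `trt_calls` objects over the same
#'   patients (either may be `NULL`).
#' @return data frame `patient_id`, `cis`, `trans`, `total`.
#' @export
trt_burden <- function(cis_calls = NULL, trans_calls = NULL) {
  pick <- Filter(Negate(is.null), list(cis_calls, trans_calls))
  if (!length(pick)) .stopf("at least one call matrix is required")
  patients <- colnames(pick[[1]]$calls)
  for (cc in pick)
    if (!identical(colnames(cc$calls), patients))
      .stopf("call matrices must share the same patients in the same order")
  count_class <- function(cc) {
    if (is.null(cc) || nrow(cc$calls) == 0L)
      return(stats::setNames(rep(0L, length(patients)), patients))
    colSums(cc$calls)
  }
  ## unordered gene-pair key, so the two directions of a convergent
  ## trans pair collapse to a single event
  pair_key <- function(cc) {
    if (is.null(cc) || nrow(cc$pairs) == 0L) return(character())
    g <- cbind(cc$pairs$upstream_gene, cc$pairs$downstream_gene)
    paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]), sep = "|")
  }
  total <- vapply(seq_along(patients), function(j) {
    keys <- character()
    for (cc in pick) {
      k <- pair_key(cc)
      if (length(k)) keys <- c(keys, k[cc$calls[, j]])
    }
    length(unique(keys))
  }, integer(1))
  data.frame(patient_id = patients,
             cis = as.integer(count_class(cis_calls)),
             trans = as.integer(count_class(trans_calls)),
             total = as.integer(total),
             stringsAsFactors = FALSE)
}

#' Compare burden between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test; exact enumeration when both groups
#' have n <= 10 and no ties, otherwise the tie-corrected normal
#' approximation (without continuity correction).
#'
#' @param values numeric vector (e.g. per-patient burden).
#' @param labels two-level factor/character vector aligned with `values`.
#' @return list with `statistic` (W), `p`, and the group sizes.
#' @export
compare_burden_groups <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    .stopf("labels must have exactly two non-empty levels")
  labels <- droplevels(labels)
  x <- values[labels == levels(labels)[1L]]
  y <- values[labels == levels(labels)[2L]]
  if (!length(x) || !length(y)) .stopf("a group is empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= 10L && length(y) <= 10L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n = c(length(x), length(y)), exact = use_exact)
}

#' Correlate burden with a numeric clinical trait
#'
#' Spearman correlation with pairwise deletion of missing trait values.
#'
#' @param burden numeric vector (per patient).
#' @param trait numeric trait aligned with `burden`; missing values are
#'   dropped pairwise.
#' @return list with `rho`, `p`, `n`; a constant trait yields missing
#'   `rho`.
#' @export
correlate_burden_trait <- function(burden, trait) {
  .spearman(as.numeric(burden), as.numeric(trait))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default (no Yates continuity correction).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param correct apply Yates continuity correction.
#' @return list with `statistic`, `p`, `df`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) .stopf("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab)))
    .stopf("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    .stopf("zero row/column marginal in the 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Read a clinical-traits table
#'
#' TSV with columns `sample_id`, `group` (`patient`/`control`) and the
#' study's trait vocabulary: `prognosis` (`death`/`remission`, patients
#' only), `virus` (`yes`/`no`), `aki` (`yes`/`no`) and numeric traits
#' (`neut_pct`, `paco2`, `pao2_fio2`, `age`, ...). Extra numeric columns
#' pass through unchanged.
#'
#' @param path TSV path.
#' @return data frame with validated vocabulary.
#' @export
read_clinical_table <- function(path) {
  cl <- read_tsv_table(path)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(cl))
  if (length(miss)) .stopf("clinical table misses columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(cl$sample_id)) .stopf("duplicate sample ids in clinical table")
  if (!all(cl$group %in% c("patient", "control")))
    .stopf("group must be 'patient' or 'control'")
  chk <- function(col, vocab) {
    if (col %in% names(cl)) {
      bad <- setdiff(stats::na.omit(unique(cl[[col]])), vocab)
      if (length(bad)) .stopf("invalid %s values: %s", col, paste(bad, collapse = ", "))
    }
  }
  chk("prognosis", c("death", "remission"))
  chk("virus", c("yes", "no"))
  chk("aki", c("yes", "no"))
  cl
}

#' Burden-versus-trait association battery
#'
#' Runs the study's trait tests on a burden table: Wilcoxon rank-sum for
#' the binary traits (prognosis, virus, aki) and Spearman correlation for
#' numeric traits, per burden class (cis, trans, total).
#'
#' @param burden table from [trt_burden()].
#' @param clinical table from [read_clinical_table()] (patients only are
#'   used).
#' @param numeric_traits trait columns to correlate (present columns
#'   only).
#' @return data frame `class`, `trait`, `test`, `statistic`, `estimate`,
#'   `p`, `n`.
#' @export
burden_trait_tests <- function(burden, clinical,
                               numeric_traits = c("neut_pct", "paco2",
                                                  "pao2_fio2", "age")) {
  cl <- clinical[match(burden$patient_id, clinical$sample_id), , drop = FALSE]
  if (anyNA(cl$sample_id))
    .stopf("burden patients missing from the clinical table")
  out <- list()
  for (cls in c("cis", "trans", "total")) {
    v <- burden[[cls]]
    for (tr in intersect(c("prognosis", "virus", "aki"), names(cl))) {
      lab <- cl[[tr]]
      ok <- !is.na(lab)
      if (length(unique(lab[ok])) == 2L) {
        w <- compare_burden_groups(v[ok], lab[ok])
        out[[length(out) + 1L]] <- data.frame(
          class = cls, trait = tr, test = "wilcoxon",
          statistic = w$statistic, estimate = NA_real_, p = w$p,
          n = sum(ok), stringsAsFactors = FALSE)
      }
    }
    for (tr in intersect(numeric_traits, names(cl))) {
      s <- correlate_burden_trait(v, cl[[tr]])
      out[[length(out) + 1L]] <- data.frame(
        class = cls, trait = tr, test = "spearman",
        statistic = NA_real_, estimate = s$rho, p = s$p, n = s$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
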