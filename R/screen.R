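## Four-step patient-specific read-through screen.
##
## Step 1 is candidate pair enumeration (annotation module). Per patient:
## step 2 keeps pairs whose upstream gene is actively expressed (FPKM
## strictly above a percentile of all candidate upstream FPKMs in that
## patient); step 3 requires the intergenic fold change over the healthy
## control baseline (FPKM*) to exceed a threshold, evidence that
## transcription ran past the TTS; step 4 requires a downstream-gene
## effect, as an absolute FPKM when the control mean is zero or as a fold
## change otherwise. A call is the conjunction of steps 2-4.

#' Screen parameter record
#'
#' All thresholds of the four-step read-through screen in one place.
#' Fold-change and percentile comparisons are strict (`>`).
#'
#' @param upstream_percentile step-2 percentile in \[0, 100\] of upstream
#'   FPKM (per patient, over all candidate pairs) a pair must exceed
#'   (default 25).
#' @param intergenic_fc_min step-3 minimum intergenic fold change over
#'   the control baseline (default 5).
#' @param downstream_abs_min step-4 absolute FPKM threshold used when the
#'   control downstream mean is zero (default 1.5).
#' @param downstream_fc_min step-4 fold-change threshold used otherwise
#'   (default 1.5).
#' @param recurrence_min_frac fraction of patients a pair must exceed to
#'   count as recurrent (default 0.30, strict).
#' @param zero_mean_epsilon pseudocount added to the control intergenic
#'   mean in step 3; with the default 0 the zero-baseline case instead
#'   uses the fallback-unit policy (see [step3_intergenic_fc()]).
#' @return list of class `screen_params`.
#' @export
screen_params <- function(upstream_percentile = 25,
                          intergenic_fc_min = 5,
                          downstream_abs_min = 1.5,
                          downstream_fc_min = 1.5,
                          recurrence_min_frac = 0.30,
                          zero_mean_epsilon = 0) {
  .assert_scalar_num(upstream_percentile, "upstream_percentile", 0, 100)
  .assert_scalar_num(intergenic_fc_min, "intergenic_fc_min", lower = 0)
  .assert_scalar_num(downstream_abs_min, "downstream_abs_min", lower = 0)
  .assert_scalar_num(downstream_fc_min, "downstream_fc_min", lower = 0)
  .assert_scalar_num(recurrence_min_frac, "recurrence_min_frac", lower = 1e-12, upper = 1)
  .assert_scalar_num(zero_mean_epsilon, "zero_mean_epsilon", lower = 0)
  structure(list(upstream_percentile = upstream_percentile,
                 intergenic_fc_min = intergenic_fc_min,
                 downstream_abs_min = downstream_abs_min,
                 downstream_fc_min = downstream_fc_min,
                 recurrence_min_frac = recurrence_min_frac,
                 zero_mean_epsilon = zero_mean_epsilon),
            class = "screen_params")
}

.fpkm_at <- function(expr, features, sample) {
  miss <- setdiff(features, expr$feature_ids)
  if (length(miss))
    .stopf("features absent from the expression matrix: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  expr$fpkm[features, sample]
}

#' Healthy-control baseline (FPKM*)
#'
#' Arithmetic mean FPKM across control samples, per feature.
#'
#' @param expr a `trt_expr` object.
#' @param control_ids control sample ids.
#' @return named numeric vector over all features.
#' @export
control_baseline <- function(expr, control_ids) {
  stopifnot(inherits(expr, "trt_expr"))
  if (!length(control_ids)) .stopf("control set is empty")
  miss <- setdiff(control_ids, expr$sample_ids)
  if (length(miss)) .stopf("unknown control samples: %s", paste(miss, collapse = ", "))
  rowMeans(expr$fpkm[, control_ids, drop = FALSE])
}

#' Step 2: actively expressed upstream genes
#'
#' Keeps candidate pairs whose upstream-gene FPKM in the given patient is
#' strictly above the `upstream_percentile`-th percentile (linear
#' interpolation, `stats::quantile` type 7) of upstream FPKM over all
#' candidate pairs in that same patient.
#'
#' @param pairs candidate pair table.
#' @param expr a `trt_expr` object.
#' @param patient_id one patient sample id.
#' @param params a [screen_params()] record.
#' @return the surviving subset of `pairs`.
#' @export
step2_expressed_upstream <- function(pairs, expr, patient_id, params = screen_params()) {
  up <- .fpkm_at(expr, pairs$upstream_gene, patient_id)
  thr <- stats::quantile(up, params$upstream_percentile / 100, type = 7, names = FALSE)
  pairs[up > thr, , drop = FALSE]
}

.fallback_unit <- function(baseline, pairs) {
  ig <- baseline[pairs$pair_id]
  nz <- ig[ig > 0]
  if (length(nz)) min(nz) else 1
}

#' Step 3: intergenic fold change over baseline
#'
#' `fc = patient intergenic FPKM / (FPKM* + zero_mean_epsilon)`. With the
#' default `zero_mean_epsilon = 0` and a zero control mean, the pair
#' fails when the patient's intergenic FPKM is also zero, and otherwise
#' passes iff that FPKM exceeds `intergenic_fc_min` times the fallback
#' unit (the smallest nonzero control intergenic mean across all
#' candidate pairs, or 1 FPKM when none exists).
#'
#' @param pair one-row pair table.
#' @param expr a `trt_expr` object.
#' @param patient_id one patient sample id.
#' @param baseline [control_baseline()] vector.
#' @param params a [screen_params()] record.
#' @param fallback_unit precomputed fallback unit; computed from
#'   `baseline` over `all_pairs` when `NULL`.
#' @param all_pairs full candidate pair table (for the fallback unit).
#' @return list with `passed` (flag) and `fc` (real, `Inf`/`NaN`-free).
#' @export
step3_intergenic_fc <- function(pair, expr, patient_id, baseline,
                                params = screen_params(),
                                fallback_unit = NULL, all_pairs = pair) {
  v <- .fpkm_at(expr, pair$pair_id, patient_id)
  b <- baseline[[pair$pair_id]]
  eps <- params$zero_mean_epsilon
  if (b + eps > 0) {
    fc <- v / (b + eps)
    return(list(passed = fc > params$intergenic_fc_min, fc = fc))
  }
  if (v == 0) return(list(passed = FALSE, fc = 0))
  if (is.null(fallback_unit)) fallback_unit <- .fallback_unit(baseline, all_pairs)
  list(passed = v > params$intergenic_fc_min * fallback_unit,
       fc = v / fallback_unit)
}

#' Step 4: downstream-gene effect
#'
#' When the control downstream mean is zero the test is absolute (FPKM >
#' `downstream_abs_min`); otherwise it is a fold change over the control
#' mean (> `downstream_fc_min`).
#'
#' @inheritParams step3_intergenic_fc
#' @return list with `passed`, `value` (the FPKM or FC compared) and
#'   `branch` (`"absolute"` or `"fold"`).
#' @export
step4_downstream_effect <- function(pair, expr, patient_id, baseline,
                                    params = screen_params()) {
  v <- .fpkm_at(expr, pair$downstream_gene, patient_id)
  b <- baseline[[pair$downstream_gene]]
  if (b == 0) {
    list(passed = v > params$downstream_abs_min, value = v, branch = "absolute")
  } else {
    fc <- v / b
    list(passed = fc > params$downstream_fc_min, value = fc, branch = "fold")
  }
}

#' Call patient-specific read-through over a pair set
#'
#' Applies steps 2-4 to every pair x patient cell; a call is their
#' conjunction. Diagnostics are recorded for every cell, including pairs
#' failing early, to support heatmap-style outputs.
#'
#' @param pairs candidate pair table (one pair class, or all pairs).
#' @param expr a `trt_expr` object covering all pair features.
#' @param patient_ids,control_ids disjoint sample id sets.
#' @param params a [screen_params()] record.
#' @return object of class `trt_calls`: list with `calls` (logical pair x
#'   patient matrix), `diagnostics` (long data frame with per-cell
#'   upstream FPKM, intergenic FC, downstream value/branch, per-step
#'   flags), `recurrence` (per-pair fraction of positive patients),
#'   `pairs`, `params`.
#' @export
call_trt <- function(pairs, expr, patient_ids, control_ids,
                     params = screen_params()) {
  stopifnot(inherits(expr, "trt_expr"))
  ids <- c(patient_ids, control_ids)
  miss <- setdiff(ids, expr$sample_ids)
  if (length(miss)) .stopf("unknown sample ids: %s", paste(miss, collapse = ", "))
  if (length(intersect(patient_ids, control_ids)))
    .stopf("patients and controls overlap")
  if (!length(patient_ids)) .stopf("no patients supplied")
  baseline <- control_baseline(expr, control_ids)
  np <- nrow(pairs)
  calls <- matrix(FALSE, nrow = np, ncol = length(patient_ids),
                  dimnames = list(pairs$pair_id, patient_ids))
  if (np == 0L) {
    return(structure(list(calls = calls,
                          diagnostics = data.frame(),
                          recurrence = numeric(), pairs = pairs,
                          params = params), class = "trt_calls"))
  }
  fb <- .fallback_unit(baseline, pairs)
  up_mat <- expr$fpkm[pairs$upstream_gene, patient_ids, drop = FALSE]
  ig_mat <- expr$fpkm[pairs$pair_id, patient_ids, drop = FALSE]
  dn_mat <- expr$fpkm[pairs$downstream_gene, patient_ids, drop = FALSE]
  ig_base <- baseline[pairs$pair_id]
  dn_base <- baseline[pairs$downstream_gene]
  eps <- params$zero_mean_epsilon

  diag_list <- vector("list", length(patient_ids))
  for (j in seq_along(patient_ids)) {
    up <- up_mat[, j]; ig <- ig_mat[, j]; dn <- dn_mat[, j]
    thr <- stats::quantile(up, params$upstream_percentile / 100,
                           type = 7, names = FALSE)
    s2 <- up > thr
    denom <- ig_base + eps
    fc_ig <- ifelse(denom > 0, ig / denom,
                    ifelse(ig > 0, ig / fb, 0))
    s3 <- ifelse(denom > 0, fc_ig > params$intergenic_fc_min,
                 ig > params$intergenic_fc_min * fb)
    branch_abs <- dn_base == 0
    dn_val <- ifelse(branch_abs, dn, dn / ifelse(branch_abs, 1, dn_base))
    s4 <- ifelse(branch_abs, dn > params$downstream_abs_min,
                 dn / ifelse(branch_abs, 1, dn_base) > params$downstream_fc_min)
    calls[, j] <- s2 & s3 & s4
    diag_list[[j]] <- data.frame(
      pair_id = pairs$pair_id, patient_id = patient_ids[j],
      upstream_fpkm = up, intergenic_fpkm = ig, intergenic_fc = fc_ig,
      downstream_fpkm = dn, downstream_value = dn_val,
      downstream_branch = ifelse(branch_abs, "absolute", "fold"),
      step2 = s2, step3 = s3, step4 = s4, call = calls[, j],
      stringsAsFactors = FALSE)
  }
  diagnostics <- do.call(rbind, diag_list)
  rownames(diagnostics) <- NULL
  structure(list(calls = calls,
                 diagnostics = diagnostics,
                 recurrence = rowMeans(calls),
                 pairs = pairs, params = params),
            class = "trt_calls")
}

#' @export
print.trt_calls <- function(x, ...) {
  cat(sprintf("<trt_calls> %d pairs x %d patients; %d positive cells; %d recurrent pairs (> %.0f%%)\n",
              nrow(x$calls), ncol(x$calls), sum(x$calls),
              length(recurrent_pairs(x)), 100 * x$params$recurrence_min_frac))
  invisible(x)
}

#' Recurrent read-through pairs
#'
#' Pairs positive in strictly more than `recurrence_min_frac` of patients.
#'
#' @param calls a `trt_calls` object.
#' @param params parameter record; defaults to the one stored in `calls`.
#' @return character vector of pair ids.
#' @export
recurrent_pairs <- function(calls, params = calls$params) {
  stopifnot(inherits(calls, "trt_calls"))
  names(calls$recurrence)[calls$recurrence > params$recurrence_min_frac]
}

#' Run the screen separately per pair class
#'
#' Applies [call_trt()] to the cis and trans subsets of the candidate
#' pairs; downstream statistics are reported per class and for their
#' union (total).
#'
#' @inheritParams call_trt
#' @return list with elements `cis`, `trans` (each a `trt_calls`) and
#'   `params`.
#' @export
screen_trt <- function(pairs, expr, patient_ids, control_ids,
                       params = screen_params()) {
  list(cis = call_trt(pairs[pairs$pair_class == "cis", , drop = FALSE],
                      expr, patient_ids, control_ids, params),
       trans = call_trt(pairs[pairs$pair_class == "trans", , drop = FALSE],
                        expr, patient_ids, control_ids, params),
       params = params)
}

#' Write screen outputs as TSV
#'
#' Emits the boolean call matrix, the long diagnostics table and the
#' recurrent-pair list.
#'
#' @param calls a `trt_calls` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (e.g. `"cis"`).
#' @return the directory, invisibly.
#' @export
write_screen_outputs <- function(calls, dir, prefix = "trt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- data.frame(pair_id = rownames(calls$calls), calls$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(cm, file.path(dir, paste0(prefix, "_calls.tsv")))
  write_tsv_table(calls$diagnostics, file.path(dir, paste0(prefix, "_diagnostics.tsv")))
  rec <- recurrent_pairs(calls)
  write_tsv_table(data.frame(pair_id = rec,
                             recurrence = calls$recurrence[rec]),
                  file.path(dir, paste0(prefix, "_recurrent.tsv")))
  invisible(dir)
}
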