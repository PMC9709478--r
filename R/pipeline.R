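## Pipeline orchestration: a validated YAML config drives
## pairs -> quantify -> screen -> stats (+ optional NETosis scoring and
## lncRNA target prediction), each stage writing TSV outputs and a JSON
## provenance record. Reruns with unchanged inputs are idempotent.

.default_pipeline_config <- function() {
  list(
    annotation = NULL,          # GTF/GFF3/BED path (or NULL with fpkm supplied)
    fragments_dir = NULL,       # directory of per-sample BED files
    fpkm = NULL,                # precomputed FPKM TSV (skips quantify)
    clinical = NULL,            # clinical TSV
    geneset = NULL,             # NETosis gene-set file (one id per line)
    binding = NULL,             # lncRNA binding-evidence TSV
    out_dir = "trt_out",
    stranded = TRUE,
    seed = 1L,
    min_intergenic_bp = 1,
    max_intergenic_bp = Inf,
    screen = unclass(screen_params()),
    run_netosis = FALSE,
    run_lnctargets = FALSE,
    lnc_window_bp = 50000,
    lnc_r_min = 0.9,
    lnc_p_max = 0.05)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), injects defaults, and reports
#' every problem at once rather than failing on the first. Unknown keys
#' warn; out-of-range values and missing input files are errors.
#'
#' @param config YAML path or named list.
#' @return validated config list of class `pipeline_config`; on failure,
#'   an error enumerating all problems.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  def <- .default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    .warnf("unknown config keys ignored: %s", paste(unknown, collapse = ", "))
  config <- config[setdiff(names(config), unknown)]
  merged <- utils::modifyList(def, config)
  if (!is.null(config$screen))
    merged$screen <- utils::modifyList(unclass(screen_params()), config$screen)

  errs <- character()
  chk_file <- function(key) {
    p <- merged[[key]]
    if (!is.null(p) && !file.exists(p))
      errs <<- c(errs, sprintf("%s: file not found (%s)", key, p))
  }
  for (k in c("annotation", "fpkm", "clinical", "geneset", "binding")) chk_file(k)
  if (!is.null(merged$fragments_dir) && !dir.exists(merged$fragments_dir))
    errs <- c(errs, sprintf("fragments_dir: directory not found (%s)", merged$fragments_dir))
  sp <- merged$screen
  rng <- function(key, lo, hi) {
    v <- sp[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi)
      errs <<- c(errs, sprintf("screen.%s: must be a number in [%s, %s]", key, lo, hi))
  }
  rng("upstream_percentile", 0, 100)
  rng("intergenic_fc_min", 0, Inf)
  rng("downstream_abs_min", 0, Inf)
  rng("downstream_fc_min", 0, Inf)
  rng("recurrence_min_frac", 1e-12, 1)
  rng("zero_mean_epsilon", 0, Inf)
  if (length(errs))
    .stopf("invalid pipeline configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  merged$screen <- do.call(screen_params, merged$screen)
  class(merged) <- "pipeline_config"
  merged
}

.provenance <- function(config, stage, inputs = character()) {
  sums <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_, "")
  list(stage = stage, seed = config$seed,
       package_version = as.character(utils::packageVersion("trtscreen")),
       inputs = as.list(sums))
}

#' Run the read-through pipeline
#'
#' Executes pair enumeration, quantification (or FPKM loading), the
#' four-step screen per pair class, burden statistics and trait tests,
#' plus optional NETosis scoring and lncRNA target prediction. Every
#' stage writes its TSVs under `out_dir` with a JSON provenance record.
#'
#' @param config path to a YAML config or a validated
#'   [validate_pipeline_config()] result.
#' @return invisible list with the in-memory stage results and the
#'   output directory.
#' @export
run_trt_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  if (is.null(config$fpkm) && (is.null(config$annotation) || is.null(config$fragments_dir)))
    .stopf("either fpkm, or annotation plus fragments_dir, must be supplied")
  if (is.null(config$clinical))
    .stopf("a clinical table is required for the screen and statistics stages")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- "annotation"
  res <- tryCatch({
    clinical <- read_clinical_table(config$clinical)
    patients <- clinical$sample_id[clinical$group == "patient"]
    controls <- clinical$sample_id[clinical$group == "control"]

    if (!is.null(config$fpkm)) {
      stage <- "load-fpkm"
      expr <- load_expression_table(config$fpkm)
      pairs <- NULL
      genes <- NULL
      if (!is.null(config$annotation)) {
        genes <- read_gene_models(config$annotation)
        pairs <- enumerate_adjacent_pairs(genes, config$min_intergenic_bp,
                                          config$max_intergenic_bp)
        pairs <- pairs[pairs$pair_id %in% expr$feature_ids &
                         pairs$upstream_gene %in% expr$feature_ids &
                         pairs$downstream_gene %in% expr$feature_ids, , drop = FALSE]
      }
      if (is.null(pairs)) .stopf("an annotation is required to define gene pairs")
    } else {
      genes <- read_gene_models(config$annotation)
      stage <- "pairs"
      pairs <- enumerate_adjacent_pairs(genes, config$min_intergenic_bp,
                                        config$max_intergenic_bp)
      stage <- "quantify"
      beds <- list.files(config$fragments_dir, pattern = "\\.bed$", full.names = TRUE)
      if (!length(beds)) .stopf("no .bed files in %s", config$fragments_dir)
      samples <- lapply(beds, read_fragments_bed)
      expr <- quantify_features(genes, pairs, samples, stranded = config$stranded)
      write_expression_table(expr, file.path(out, "fpkm.tsv"))
    }
    write_tsv_table(pairs, file.path(out, "pairs.tsv"))

    stage <- "screen"
    scr <- screen_trt(pairs, expr, patients, controls, config$screen)
    write_screen_outputs(scr$cis, out, "cis")
    write_screen_outputs(scr$trans, out, "trans")

    stage <- "stats"
    burden <- trt_burden(scr$cis, scr$trans)
    write_tsv_table(burden, file.path(out, "burden.tsv"))
    tests <- burden_trait_tests(burden, clinical)
    write_tsv_table(tests, file.path(out, "burden_trait_tests.tsv"))
    baseline <- control_baseline(expr, controls)
    rec <- c(recurrent_pairs(scr$cis), recurrent_pairs(scr$trans))
    fc_cor <- fc_correlation_per_pair(rec, pairs, expr, baseline, patients)
    write_tsv_table(fc_cor, file.path(out, "fc_correlation.tsv"))

    netosis <- NULL
    if (isTRUE(config$run_netosis)) {
      stage <- "netosis"
      gene_set <- readLines(config$geneset)
      sel <- select_expressed_genes(expr, gene_set, patients)
      sc <- pc1_score(expr, sel, patients)
      sc <- orient_and_diagnose(sc, expr)
      assoc <- associate_score_traits(sc, clinical)
      write_tsv_table(data.frame(sample_id = names(sc$scores),
                                 pc1 = as.numeric(sc$scores)),
                      file.path(out, "netosis_pc1.tsv"))
      write_tsv_table(data.frame(gene_id = names(sc$gene_cor),
                                 loading = as.numeric(sc$loadings),
                                 cor_with_pc1 = as.numeric(sc$gene_cor)),
                      file.path(out, "netosis_loadings.tsv"))
      write_tsv_table(assoc, file.path(out, "netosis_trait_tests.tsv"))
      netosis <- list(score = sc, assoc = assoc)
    }

    lnct <- NULL
    if (isTRUE(config$run_lnctargets) && !is.null(genes)) {
      stage <- "lnctargets"
      is_lnc <- !is.na(genes$biotype) & genes$biotype == "lncRNA"
      if (any(is_lnc)) {
        cis <- cis_targets(genes[is_lnc, ], genes[!is_lnc, ],
                           window_bp = config$lnc_window_bp)
        trans <- trans_coexpression_targets(
          expr$fpkm[genes$gene_id[is_lnc], , drop = FALSE],
          expr$fpkm[genes$gene_id[!is_lnc], , drop = FALSE],
          r_min = config$lnc_r_min, p_max = config$lnc_p_max)
        if (!is.null(config$binding))
          trans <- intersect_binding(trans, config$binding)
        lnct <- rbind(
          data.frame(cis, coexpression_R = NA_real_, p = NA_real_,
                     binding_supported = NA),
          data.frame(trans[c("lnc_id", "target_gene_id", "mode")],
                     distance_bp = NA_real_,
                     trans[c("coexpression_R", "p", "binding_supported")]))
        write_tsv_table(lnct, file.path(out, "lnc_targets.tsv"))
      }
    }

    prov <- .provenance(config, "pipeline",
                        inputs = unlist(config[c("annotation", "fpkm",
                                                 "clinical", "geneset",
                                                 "binding")], use.names = FALSE))
    writeLines(.to_json(prov), file.path(out, "provenance.json"))
    list(pairs = pairs, expr = expr, screen = scr, burden = burden,
         tests = tests, fc_correlation = fc_cor, netosis = netosis,
         lnc_targets = lnct, out_dir = out)
  }, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}

## minimal JSON serializer for the provenance record (flat lists,
## strings and numbers only)
.to_json <- function(x) {
  enc <- function(v) {
    if (is.list(v)) {
      if (is.null(names(v)))
        paste0("[", paste(vapply(v, enc, ""), collapse = ","), "]")
      else
        paste0("{", paste(sprintf('"%s":%s', names(v),
                                  vapply(v, enc, "")), collapse = ","), "}")
    } else if (is.character(v)) {
      if (length(v) != 1L) return(enc(as.list(v)))
      if (is.na(v)) "null" else sprintf('"%s"', gsub('"', '\\\\"', v))
    } else if (is.numeric(v) || is.logical(v)) {
      if (length(v) != 1L) return(enc(as.list(v)))
      if (is.na(v)) "null" else tolower(format(v, scientific = FALSE))
    } else "null"
  }
  enc(x)
}
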