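## Seeded synthetic-cohort generator with planted read-through events.
##
## The generator works counts-first: expected fragment counts per
## feature are drawn, Poisson-sampled per sample, and converted to FPKM
## with the realized library sizes. Fragment materialization
## (simulate_fragments) places exactly those counts as intervals, with
## read-through fragments spanning TTS -> intergenic -> downstream gene
## start on the upstream strand, so re-quantifying the fragments
## reproduces the count-mode structure.
##
## Planted events: in patients only, selected gene pairs receive
## intergenic coverage calibrated to `readthrough_intensity` times the
## control background and a coupled downstream-gene boost calibrated to
## `downstream_coupling`, with shared lognormal jitter so intergenic and
## downstream fold changes are rank-correlated across patients. A
## co-regulated NETosis gene block is elevated in a patient subset, and
## clinical traits are coupled to the true burden and block activity via
## a Gaussian copula.

#' Simulation configuration
#'
#' Defaults describe the cohort regime the screen is designed for:
#' a 40-patient / 20-control cohort over ~500 candidate pairs with 50
#' planted read-through events at intergenic fold change 10 and
#' downstream fold change 3.
#'
#' @param seed integer RNG seed; fully determines all outputs.
#' @param n_chromosomes,genes_per_chromosome genome shape.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length
#'   (bp).
#' @param intergenic_meanlog,intergenic_sdlog log-normal intergenic gap
#'   length (bp).
#' @param n_patients,n_controls cohort sizes.
#' @param base_count_meanlog,base_count_sdlog log-normal expected
#'   fragment count per gene per sample.
#' @param intergenic_bg_count expected background fragments per
#'   intergenic interval per sample (leaky transcription).
#' @param n_trt_pairs_planted number of planted read-through pairs.
#' @param readthrough_intensity target intergenic fold change over the
#'   control background (default 10).
#' @param downstream_coupling target downstream-gene fold change
#'   (default 3).
#' @param readthrough_jitter_sd lognormal sd of the per-cell jitter
#'   shared by the intergenic and downstream signals.
#' @param coupling_noise_sd lognormal sd of downstream-only noise; with
#'   the jitter it sets the intergenic/downstream fold-change rank
#'   correlation across patients.
#' @param trt_patient_frac expected fraction of patients in which a
#'   planted pair is active.
#' @param upstream_sel_quantile planted pairs are drawn among pairs whose
#'   upstream gene's baseline expression is above this quantile
#'   (read-through arises at actively transcribed genes).
#' @param netosis_block_genes,netosis_low_genes sizes of the elevated
#'   NETosis block and of additional weakly expressed set members.
#' @param netosis_active_frac fraction of patients with the block
#'   elevated.
#' @param netosis_log2_effect log2 expression shift of the block in
#'   active patients.
#' @param death_frac,virus_frac,aki_frac marginal label frequencies for
#'   patients.
#' @param prognosis_effect multiplicative shift of the per-patient
#'   planting probability (hence burden) in the death group; 1 = null.
#' @param neut_rho,paco2_rho,pao2fio2_rho Gaussian-copula correlation
#'   targets for (burden, NEUT%), (block activity, PaCO2) and (block
#'   activity, PaO2/FiO2; applied with negative sign).
#' @param fragment_length fragment span used when materializing
#'   intervals (bp).
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L,
                              genes_per_chromosome = 126L,
                              gene_length_meanlog = log(1500),
                              gene_length_sdlog = 0.4,
                              intergenic_meanlog = log(1200),
                              intergenic_sdlog = 0.5,
                              n_patients = 40L,
                              n_controls = 20L,
                              base_count_meanlog = log(30),
                              base_count_sdlog = 1,
                              intergenic_bg_count = 6,
                              n_trt_pairs_planted = 50L,
                              readthrough_intensity = 10,
                              downstream_coupling = 3,
                              readthrough_jitter_sd = 0.25,
                              coupling_noise_sd = 0.3,
                              trt_patient_frac = 0.6,
                              upstream_sel_quantile = 0.5,
                              netosis_block_genes = 30L,
                              netosis_low_genes = 10L,
                              netosis_active_frac = 0.5,
                              netosis_log2_effect = 1.5,
                              death_frac = 0.268,
                              virus_frac = 0.393,
                              aki_frac = 0.321,
                              prognosis_effect = 2,
                              neut_rho = 0.4,
                              paco2_rho = 0.4,
                              pao2fio2_rho = 0.35,
                              fragment_length = 250L) {
  cfg <- as.list(environment())
  for (nm in c("n_chromosomes", "genes_per_chromosome", "n_patients",
               "n_controls", "n_trt_pairs_planted", "netosis_block_genes"))
    .assert_scalar_num(cfg[[nm]], nm, lower = 1)
  .assert_scalar_num(trt_patient_frac, "trt_patient_frac", 1e-9, 1)
  .assert_scalar_num(netosis_active_frac, "netosis_active_frac", 1e-9, 1)
  .assert_scalar_num(readthrough_intensity, "readthrough_intensity", lower = 0)
  .assert_scalar_num(downstream_coupling, "downstream_coupling", lower = 0)
  .assert_scalar_num(prognosis_effect, "prognosis_effect", lower = 0)
  structure(cfg, class = "sim_config")
}

#' Preset simulation configurations
#'
#' `"tiny"` (20 genes, 6 samples) runs in seconds and drives
#' integration tests; `"default"` is the analysis-scale cohort;
#' `"large"` stresses scaling behaviour.
#'
#' @param preset `"tiny"`, `"default"`, or `"large"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [simulation_config()].
#' @return a `sim_config`.
#' @export
sim_preset <- function(preset = c("default", "tiny", "large"), seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    tiny = list(n_chromosomes = 2L, genes_per_chromosome = 10L,
                n_patients = 4L, n_controls = 2L,
                n_trt_pairs_planted = 4L,
                netosis_block_genes = 4L, netosis_low_genes = 2L),
    default = list(),
    large = list(n_chromosomes = 8L, genes_per_chromosome = 200L,
                 n_patients = 80L, n_controls = 40L,
                 n_trt_pairs_planted = 120L))
  do.call(simulation_config, c(list(seed = seed), args, list(...)))
}

#' Simulate a gene annotation
#'
#' Genes are laid out sequentially per chromosome with log-normal
#' lengths and gaps and random strands, so same-strand, convergent and
#' divergent neighbours all arise. Candidate pairs are enumerated with
#' [enumerate_adjacent_pairs()].
#'
#' @param config a [simulation_config()].
#' @return list with `genes` ([gene_models()]) and `pairs`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .simulate_genome_impl(config)
}

.simulate_genome_impl <- function(config) {
  rows <- list()
  gidx <- 0L
  for (ch in seq_len(config$n_chromosomes)) {
    pos <- 1000
    for (k in seq_len(config$genes_per_chromosome)) {
      len <- max(200, round(stats::rlnorm(1, config$gene_length_meanlog,
                                          config$gene_length_sdlog)))
      gap <- max(100, round(stats::rlnorm(1, config$intergenic_meanlog,
                                          config$intergenic_sdlog)))
      gidx <- gidx + 1L
      rows[[gidx]] <- data.frame(
        gene_id = sprintf("g%04d", gidx), chrom = paste0("chr", ch),
        start = pos, end = pos + len,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      pos <- pos + len + gap
    }
  }
  df <- do.call(rbind, rows)
  genes <- gene_models(df$gene_id, df$chrom, df$start, df$end, df$strand)
  list(genes = genes, pairs = enumerate_adjacent_pairs(genes))
}

## Patient latents, labels and planted events; everything downstream of
## the genome that defines the ground truth.
.simulate_ground_truth_impl <- function(genes, pairs, config) {
  n_pat <- config$n_patients
  patient_ids <- sprintf("P%02d", seq_len(n_pat))
  control_ids <- sprintf("C%02d", seq_len(config$n_controls))

  ## per-gene baseline expected counts and true FPKM
  lambda <- stats::setNames(
    stats::rlnorm(nrow(genes), config$base_count_meanlog, config$base_count_sdlog),
    genes$gene_id)

  ## NETosis gene set: an elevated block plus weakly expressed members,
  ## drawn from genes not involved in planted pairs (chosen below)
  up_fpkm <- lambda[pairs$upstream_gene] / (genes$length_bp[match(pairs$upstream_gene, genes$gene_id)] / 1000)
  thr <- stats::quantile(up_fpkm, config$upstream_sel_quantile, names = FALSE)
  eligible <- which(up_fpkm > thr)
  ## avoid planting both directions over the same gap
  ukey <- paste(pmin(pairs$upstream_gene, pairs$downstream_gene),
                pmax(pairs$upstream_gene, pairs$downstream_gene), sep = "|")
  keep <- !duplicated(ukey)
  eligible <- eligible[keep[eligible]]
  n_plant <- min(config$n_trt_pairs_planted, length(eligible))
  planted_idx <- sort(sample(eligible, n_plant))
  planted_ids <- pairs$pair_id[planted_idx]
  planted_genes <- unique(c(pairs$upstream_gene[planted_idx],
                            pairs$downstream_gene[planted_idx]))

  pool <- setdiff(genes$gene_id, planted_genes)
  n_block <- min(config$netosis_block_genes, length(pool))
  block_genes <- sort(sample(pool, n_block))
  pool2 <- setdiff(pool, block_genes)
  n_low <- min(config$netosis_low_genes, length(pool2))
  low_genes <- sort(sample(pool2, n_low))
  lambda[low_genes] <- 0.05  # near-silent set members exercise the prevalence filter

  ## prognosis labels first; they shift the planting probability
  n_death <- max(1L, round(config$death_frac * n_pat))
  prognosis <- rep("remission", n_pat)
  prognosis[sample(n_pat, n_death)] <- "death"
  e <- config$prognosis_effect
  d <- n_death / n_pat
  p_rem <- min(0.95, config$trt_patient_frac / (1 - d + e * d))
  p_active <- ifelse(prognosis == "death", pmin(0.95, e * p_rem), p_rem)

  ## NETosis latent activity and active subset
  z_net <- stats::rnorm(n_pat)
  active_thr <- stats::quantile(z_net, 1 - config$netosis_active_frac, names = FALSE)
  netosis_active <- z_net > active_thr

  ## planted cells and their shared jitter / downstream noise
  active <- matrix(stats::runif(n_plant * n_pat) < rep(p_active, each = n_plant),
                   nrow = n_plant, dimnames = list(planted_ids, patient_ids))
  jitter <- matrix(stats::rlnorm(n_plant * n_pat, 0, config$readthrough_jitter_sd),
                   nrow = n_plant, dimnames = list(planted_ids, patient_ids))
  dnoise <- matrix(stats::rlnorm(n_plant * n_pat, 0, config$coupling_noise_sd),
                   nrow = n_plant, dimnames = list(planted_ids, patient_ids))

  list(patient_ids = patient_ids, control_ids = control_ids,
       lambda = lambda,
       planted_pair_ids = planted_ids,
       active = active, jitter = jitter, dnoise = dnoise,
       true_burden = stats::setNames(colSums(active), patient_ids),
       prognosis = stats::setNames(prognosis, patient_ids),
       netosis_block_genes = block_genes,
       netosis_gene_set = c(block_genes, low_genes),
       netosis_active = stats::setNames(netosis_active, patient_ids),
       z_net = stats::setNames(z_net, patient_ids))
}

## Expected counts per feature x sample implied by the ground truth.
## Rows: genes then directed-pair intergenic features. Read-through
## counts land on the intergenic interval and the upstream gene; they
## reach the downstream gene's (sense) count only for cis pairs.
.expected_counts <- function(genes, pairs, gt, config) {
  samples <- c(gt$patient_ids, gt$control_ids)
  nG <- nrow(genes); nP <- nrow(pairs)
  lam <- matrix(rep(gt$lambda[genes$gene_id], length(samples)), nrow = nG,
                dimnames = list(genes$gene_id, samples))
  mult <- 2^config$netosis_log2_effect
  act_pat <- names(gt$netosis_active)[gt$netosis_active]
  lam[gt$netosis_block_genes, act_pat] <- lam[gt$netosis_block_genes, act_pat] * mult
  ig <- matrix(config$intergenic_bg_count, nrow = nP, ncol = length(samples),
               dimnames = list(pairs$pair_id, samples))
  rt <- matrix(0, nrow = nP, ncol = length(samples),
               dimnames = list(pairs$pair_id, samples))  # read-through expectation
  dx <- matrix(0, nrow = nG, ncol = length(samples),
               dimnames = list(genes$gene_id, samples))  # downstream boost expectation
  if (length(gt$planted_pair_ids)) {
    pidx <- match(gt$planted_pair_ids, pairs$pair_id)
    bg <- config$intergenic_bg_count
    ## fold changes are FPKM ratios, and the planted signal itself
    ## inflates patient library sizes; calibrate the planted counts to
    ## the target FPKM fold change by iterating the implied library
    ## inflation factor per patient (two passes converge closely)
    lib_ctl <- mean(colSums(lam[, gt$control_ids, drop = FALSE])) + nP * bg
    infl <- stats::setNames(rep(1, length(gt$patient_ids)), gt$patient_ids)
    infl_prev <- infl
    for (pass in 1:25) {
      rt[] <- 0; dx[] <- 0
      for (k in seq_along(pidx)) {
        i <- pidx[k]
        on <- gt$active[k, ]          # over patients
        if (!any(on)) next
        pats <- gt$patient_ids[on]
        J <- gt$jitter[k, on]; E <- gt$dnoise[k, on]
        rt[i, pats] <- bg * pmax(0, config$readthrough_intensity * J * infl[pats] - 1)
        dn <- pairs$downstream_gene[i]
        dx[dn, pats] <- dx[dn, pats] + gt$lambda[[dn]] *
          pmax(0, config$downstream_coupling * J * E * infl[pats] - 1)
      }
      lib_pat <- colSums(lam[, gt$patient_ids, drop = FALSE]) + nP * bg +
        colSums(rt[, gt$patient_ids, drop = FALSE]) +
        colSums(dx[, gt$patient_ids, drop = FALSE])
      infl <- lib_pat / lib_ctl
      if (max(abs(infl - infl_prev)) < 1e-8) break
      infl_prev <- infl
    }
  }
  list(gene = lam, gene_extra = dx, intergenic = ig, readthrough = rt,
       samples = samples)
}

## Poisson-realized counts assembled into the feature x sample matrix.
.realize_counts <- function(genes, pairs, exp_counts) {
  draw <- function(m) {
    out <- matrix(stats::rpois(length(m), m), nrow = nrow(m),
                  dimnames = dimnames(m))
    out
  }
  gene_base <- draw(exp_counts$gene)
  gene_extra <- draw(exp_counts$gene_extra)
  ig_bg <- draw(exp_counts$intergenic)
  rt <- draw(exp_counts$readthrough)
  ## read-through fragments also cover the upstream gene body and, for
  ## cis pairs, the downstream gene's sense strand
  gene_cnt <- gene_base + gene_extra
  for (i in seq_len(nrow(pairs))) {
    if (!any(rt[i, ] > 0)) next
    up <- pairs$upstream_gene[i]
    gene_cnt[up, ] <- gene_cnt[up, ] + rt[i, ]
    if (pairs$pair_class[i] == "cis") {
      dn <- pairs$downstream_gene[i]
      gene_cnt[dn, ] <- gene_cnt[dn, ] + rt[i, ]
    }
  }
  list(gene = gene_cnt, intergenic = ig_bg + rt,
       gene_base = gene_base, gene_extra = gene_extra,
       ig_bg = ig_bg, readthrough = rt)
}

.counts_to_expr <- function(genes, pairs, counts) {
  cnt <- rbind(counts$gene, counts$intergenic)
  lens <- c(genes$length_bp, pairs$intergenic_length)
  lib <- pmax(1, colSums(cnt))
  fp <- sweep(cnt / lens * 1000, 2, lib / 1e6, "/")
  expression_matrix(fp, lib,
                    feature_type = c(rep("gene", nrow(genes)),
                                     rep("intergenic", nrow(pairs))),
                    counts = cnt)
}

#' Simulate a full cohort
#'
#' One-shot generator: genome, ground truth, per-feature counts, FPKM
#' matrix and clinical table, all determined by `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param fragments also materialize per-sample fragment intervals
#'   (slower; needed to exercise the quantification stage end to end).
#' @return list with `genes`, `pairs`, `expr` (`trt_expr`), `clinical`,
#'   `netosis_gene_set`, `ground_truth`, `config`, and (optionally)
#'   `fragment_sets`.
#' @export
simulate_trt_cohort <- function(config = simulation_config(), fragments = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- .simulate_genome_impl(config)
  gt <- .simulate_ground_truth_impl(genome$genes, genome$pairs, config)
  expc <- .expected_counts(genome$genes, genome$pairs, gt, config)
  counts <- .realize_counts(genome$genes, genome$pairs, expc)
  expr <- .counts_to_expr(genome$genes, genome$pairs, counts)
  clinical <- .simulate_clinical_impl(gt, config)
  out <- list(genes = genome$genes, pairs = genome$pairs, expr = expr,
              clinical = clinical, netosis_gene_set = gt$netosis_gene_set,
              ground_truth = gt, config = config)
  if (fragments)
    out$fragment_sets <- .materialize_fragments(genome$genes, genome$pairs,
                                                counts, config)
  out
}

#' Simulate per-sample fragment intervals
#'
#' Materializes a cohort's counts as fragment intervals: gene fragments
#' fall inside gene bodies on the gene strand, intergenic background
#' falls inside the gap on the upstream strand, and read-through
#' fragments span from just before the upstream TTS across the gap into
#' the downstream gene on the upstream strand.
#'
#' @param config a [simulation_config()].
#' @return list with `fragment_sets` (list of [fragment_set()]),
#'   `genes`, `pairs`, `expr`, `ground_truth`, `clinical`, matching
#'   [simulate_trt_cohort()] output.
#' @export
simulate_fragments <- function(config = simulation_config()) {
  simulate_trt_cohort(config, fragments = TRUE)
}

.materialize_fragments <- function(genes, pairs, counts, config) {
  fl <- config$fragment_length
  samples <- colnames(counts$gene)
  gstart <- genes$start; gend <- genes$end
  names(gstart) <- names(gend) <- genes$gene_id
  gstrand <- stats::setNames(genes$strand, genes$gene_id)

  place_within <- function(chrom, s, e, n, strand) {
    if (n == 0L) return(NULL)
    len <- min(fl, e - s)
    starts <- if (e - s - len > 0) s + floor(stats::runif(n, 0, e - s - len + 1)) else rep(s, n)
    data.frame(chrom = chrom, start = starts, end = starts + len,
               strand = strand, stringsAsFactors = FALSE)
  }

  out <- vector("list", length(samples))
  names(out) <- samples
  gidx <- match(genes$gene_id, rownames(counts$gene))
  for (s in samples) {
    chunks <- list()
    ## gene-body fragments (base + induced downstream boost)
    n_gene <- counts$gene_base[, s] + counts$gene_extra[, s]
    for (i in which(n_gene > 0L)) {
      chunks[[length(chunks) + 1L]] <-
        place_within(genes$chrom[i], genes$start[i], genes$end[i],
                     n_gene[i], genes$strand[i])
    }
    ## intergenic background on the upstream strand
    n_bg <- counts$ig_bg[, s]
    for (i in which(n_bg > 0L)) {
      chunks[[length(chunks) + 1L]] <-
        place_within(pairs$chrom[i], pairs$intergenic_start[i],
                     pairs$intergenic_end[i], n_bg[i], pairs$upstream_strand[i])
    }
    ## read-through fragments spanning TTS -> gap -> downstream start
    n_rt <- counts$readthrough[, s]
    for (i in which(n_rt > 0L)) {
      up <- pairs$upstream_gene[i]; dn <- pairs$downstream_gene[i]
      if (pairs$upstream_strand[i] == "+") {
        fs <- max(gstart[[up]], gend[[up]] - 100)
        fe <- min(gend[[dn]], pairs$intergenic_end[i] + 100)
      } else {
        fs <- max(gstart[[dn]], pairs$intergenic_start[i] - 100)
        fe <- min(gend[[up]], gstart[[up]] + 100)
      }
      chunks[[length(chunks) + 1L]] <- data.frame(
        chrom = pairs$chrom[i], start = rep(fs, n_rt[i]),
        end = rep(fe, n_rt[i]), strand = pairs$upstream_strand[i],
        stringsAsFactors = FALSE)
    }
    fr <- if (length(chunks)) do.call(rbind, chunks) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 strand = character(), stringsAsFactors = FALSE)
    out[[s]] <- fragment_set(s, fr)
  }
  out
}

## Clinical traits coupled to the ground truth through a Gaussian copula:
## normal scores of the coupling variable are mixed with independent
## noise at the configured correlation, then mapped to the trait's
## marginal.
.simulate_clinical_impl <- function(gt, config) {
  n_pat <- length(gt$patient_ids)
  z_burden <- stats::qnorm((rank(gt$true_burden, ties.method = "average") - 0.5) / n_pat)
  z_net <- as.numeric(gt$z_net)
  mix <- function(z, rho) rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z))
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

  neut <- clamp(86 + 6 * mix(z_burden, config$neut_rho), 40, 100)
  paco2 <- clamp(36 + 6 * mix(z_net, config$paco2_rho), 15, 90)
  pf <- clamp(170 + 75 * mix(-z_net, config$pao2fio2_rho), 40, 500)
  age <- round(clamp(52 + 15 * stats::rnorm(n_pat), 18, 90))
  virus <- ifelse(stats::runif(n_pat) <
                    stats::plogis(stats::qlogis(config$virus_frac) +
                                    z_net + 0.5 * z_burden), "yes", "no")
  aki <- ifelse(stats::runif(n_pat) <
                  stats::plogis(stats::qlogis(config$aki_frac) + z_net),
                "yes", "no")
  pat <- data.frame(sample_id = gt$patient_ids, group = "patient",
                    prognosis = as.character(gt$prognosis),
                    virus = virus, aki = aki,
                    neut_pct = round(neut, 1), paco2 = round(paco2, 1),
                    pao2_fio2 = round(pf, 1), age = age,
                    stringsAsFactors = FALSE)
  n_ctl <- length(gt$control_ids)
  ctl <- data.frame(sample_id = gt$control_ids, group = "control",
                    prognosis = NA_character_, virus = "no", aki = "no",
                    neut_pct = round(clamp(55 + 8 * stats::rnorm(n_ctl), 30, 80), 1),
                    paco2 = round(clamp(38 + 3 * stats::rnorm(n_ctl), 25, 50), 1),
                    pao2_fio2 = round(clamp(420 + 40 * stats::rnorm(n_ctl), 300, 550), 1),
                    age = round(clamp(40 + 12 * stats::rnorm(n_ctl), 18, 80)),
                    stringsAsFactors = FALSE)
  rbind(pat, ctl)
}

#' Simulate a clinical table for an existing ground truth
#'
#' @param ground_truth ground-truth list from [simulate_trt_cohort()].
#' @param config the matching [simulation_config()].
#' @return clinical data frame (see [read_clinical_table()] layout).
#' @export
simulate_clinical <- function(ground_truth, config) {
  .simulate_clinical_impl(ground_truth, config)
}

.write_gtf <- function(genes, path) {
  attr_field <- sprintf('gene_id "%s";', genes$gene_id)
  lines <- paste(genes$chrom, "trtscreen", "gene",
                 format(genes$start + 1, scientific = FALSE, trim = TRUE),
                 format(genes$end, scientific = FALSE, trim = TRUE),
                 ".", genes$strand, ".", attr_field, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete fixture bundle
#'
#' Emits every input the pipeline stages consume: gene annotation (GTF),
#' per-sample fragment BEDs, FPKM TSV with library-size sidecar,
#' clinical TSV, NETosis gene-set file, and ground-truth TSVs. Rerunning
#' with the same config reproduces identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created).
#' @param fragments write per-sample fragment BEDs (default `TRUE`).
#' @return invisible list of written paths.
#' @export
write_fixture_bundle <- function(config, out_dir, fragments = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_trt_cohort(config, fragments = fragments)
  paths <- list()
  paths$annotation <- file.path(out_dir, "genes.gtf")
  .write_gtf(cohort$genes, paths$annotation)
  paths$pairs <- file.path(out_dir, "pairs.tsv")
  write_tsv_table(cohort$pairs, paths$pairs)
  paths$fpkm <- file.path(out_dir, "fpkm.tsv")
  write_expression_table(cohort$expr, paths$fpkm)
  paths$clinical <- file.path(out_dir, "clinical.tsv")
  write_tsv_table(cohort$clinical, paths$clinical)
  paths$geneset <- file.path(out_dir, "netosis_genes.txt")
  writeLines(cohort$netosis_gene_set, paths$geneset)
  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  gt <- cohort$ground_truth
  act <- data.frame(pair_id = rep(rownames(gt$active), ncol(gt$active)),
                    patient_id = rep(colnames(gt$active), each = nrow(gt$active)),
                    active = as.vector(gt$active))
  paths$ground_truth_active <- file.path(gt_dir, "planted_active.tsv")
  write_tsv_table(act, paths$ground_truth_active)
  paths$ground_truth_burden <- file.path(gt_dir, "true_burden.tsv")
  write_tsv_table(data.frame(patient_id = names(gt$true_burden),
                             true_burden = as.integer(gt$true_burden),
                             prognosis = as.character(gt$prognosis),
                             netosis_active = as.logical(gt$netosis_active)),
                  paths$ground_truth_burden)
  if (fragments) {
    frag_dir <- file.path(out_dir, "fragments")
    dir.create(frag_dir, showWarnings = FALSE)
    for (s in names(cohort$fragment_sets)) {
      fs <- cohort$fragment_sets[[s]]
      p <- file.path(frag_dir, paste0(s, ".bed"))
      bed <- data.frame(fs$fragments$chrom,
                        format(fs$fragments$start, scientific = FALSE, trim = TRUE),
                        format(fs$fragments$end, scientific = FALSE, trim = TRUE),
                        paste0(s, "_f", seq_len(nrow(fs$fragments))),
                        0L, fs$fragments$strand)
      utils::write.table(bed, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      paths[[paste0("fragments_", s)]] <- p
    }
  }
  invisible(paths)
}
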