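## Independent brute-force oracles and fixture builders used across the
## suite. Oracles deliberately avoid the package's code paths.

## naive all-pairs interval overlap count (>= 1 bp, half-open coords)
naive_overlap_count <- function(iv, frags, stranded = TRUE) {
  vapply(seq_len(nrow(iv)), function(i) {
    hit <- frags$chrom == iv$chrom[i] &
      frags$start < iv$end[i] & frags$end > iv$start[i]
    if (stranded) hit <- hit & frags$strand == iv$strand[i]
    sum(hit)
  }, numeric(1))
}

## O(n^2) adjacency oracle: two genes are coordinate-consecutive on a
## chromosome iff no third gene's start lies strictly between their
## starts; orientation follows the TTS-borders-gap rule.
naive_adjacent_pairs <- function(genes, min_bp = 1, max_bp = Inf) {
  out <- list()
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(genes))) {
    if (i == j) next
    a <- genes[i, ]; b <- genes[j, ]
    if (a$chrom != b$chrom) next
    if (a$start > b$start) next            # a is the left gene
    between <- genes$chrom == a$chrom & genes$start > a$start &
      genes$start < b$start & genes$gene_id != a$gene_id &
      genes$gene_id != b$gene_id
    if (any(between)) next
    gap_s <- a$end; gap_e <- b$start
    len <- gap_e - gap_s
    if (len < min_bp || len > max_bp) next
    if (a$strand == "+")                    # left gene's TTS borders gap
      out[[length(out) + 1L]] <- data.frame(
        upstream_gene = a$gene_id, downstream_gene = b$gene_id,
        pair_class = if (a$strand == b$strand) "cis" else "trans",
        intergenic_start = gap_s, intergenic_end = gap_e)
    if (b$strand == "-")                    # right gene's TTS borders gap
      out[[length(out) + 1L]] <- data.frame(
        upstream_gene = b$gene_id, downstream_gene = a$gene_id,
        pair_class = if (a$strand == b$strand) "cis" else "trans",
        intergenic_start = gap_s, intergenic_end = gap_e)
  }
  if (!length(out)) return(data.frame(upstream_gene = character(),
                                      downstream_gene = character(),
                                      pair_class = character(),
                                      intergenic_start = numeric(),
                                      intergenic_end = numeric()))
  do.call(rbind, out)
}

## random annotation with distinct starts and non-overlapping bodies
random_gene_models <- function(n, chroms = c("chrA", "chrB")) {
  rows <- lapply(chroms, function(ch) {
    k <- max(1L, rpois(1, n / length(chroms)))
    pos <- 0
    do.call(rbind, lapply(seq_len(k), function(i) {
      pos <<- pos + sample(50:500, 1)
      s <- pos
      len <- sample(100:400, 1)
      pos <<- pos + len
      data.frame(chrom = ch, start = s, end = s + len,
                 strand = sample(c("+", "-"), 1))
    }))
  })
  df <- do.call(rbind, rows)
  df$gene_id <- sprintf("G%03d", seq_len(nrow(df)))
  gene_models(df$gene_id, df$chrom, df$start, df$end, df$strand)
}

## Spearman rho by explicit average-rank computation (Pearson on ranks)
spearman_rank_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## two-sided exact Wilcoxon rank-sum p by full enumeration of group
## assignments (no ties assumed)
wilcoxon_exact_oracle <- function(x, y) {
  all <- c(x, y)
  n <- length(all); nx <- length(x)
  r <- rank(all)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

## first principal component via direct eigendecomposition of the
## covariance (or correlation) matrix of a samples x genes layout
pc1_eigen_oracle <- function(m, scale. = TRUE) {
  mm <- scale(m, center = TRUE, scale = scale.)
  cv <- crossprod(mm) / (nrow(mm) - 1)
  e <- eigen(cv, symmetric = TRUE)
  list(loadings = e$vectors[, 1], scores = mm %*% e$vectors[, 1],
       variance_explained = e$values[1] / sum(e$values))
}

## rank-based AUC of score for the positive class
rank_auc <- function(score, positive) {
  r <- rank(score)
  (sum(r[positive]) - sum(positive) * (sum(positive) + 1) / 2) /
    (sum(positive) * sum(!positive))
}

## build a trt_expr directly from an FPKM matrix
make_expr <- function(m, feature_type = NULL, lib = NULL) {
  if (is.null(lib)) lib <- stats::setNames(rep(1e6, ncol(m)), colnames(m))
  expression_matrix(m, lib, feature_type = feature_type)
}

## small fixed two-gene / one-pair screen scenario used by screen tests:
## one patient carries a planted read-through, the second does not
toy_screen_fixture <- function() {
  genes <- gene_models(c("up", "dn", "other1", "other2", "other3"),
                       "chr1",
                       c(100, 500, 2000, 4000, 6000),
                       c(300, 800, 2500, 4500, 6400),
                       c("+", "+", "+", "+", "+"))
  pairs <- enumerate_adjacent_pairs(genes)
  feat <- c(genes$gene_id, pairs$pair_id)
  m <- matrix(0, nrow = length(feat), ncol = 4,
              dimnames = list(feat, c("P1", "P2", "C1", "C2")))
  ## all genes moderately expressed everywhere
  m[genes$gene_id, ] <- 5
  m["up", c("P1", "P2")] <- c(50, 50)
  ## intergenic: controls quiet, P1 hot
  m[pairs$pair_id, ] <- 0.5
  ig <- pairs$pair_id[pairs$upstream_gene == "up"]
  m[ig, "P1"] <- 6          # FC 12 over control mean 0.5
  m["dn", "P1"] <- 12       # FC 2.4 over control mean 5
  list(genes = genes, pairs = pairs, expr = make_expr(m),
       planted_pair = ig)
}
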