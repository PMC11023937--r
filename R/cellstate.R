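#' Quality-control filter for single cells
#'
#' Keeps cells with at least `min_rna` RNA reads and at least `min_dna` DNA
#' reads.
#'
#' @param cells Tibble with `n_rna` and `n_dna` per cell.
#' @param min_rna,min_dna Inclusive thresholds.
#' @return List: `kept` (filtered tibble), `report` (counts by reason).
#' @export
filter_cells <- function(cells, min_rna = 100L, min_dna = 5000L) {
  keep <- cells$n_rna >= min_rna & cells$n_dna >= min_dna
  list(kept = cells[keep, ],
       report = list(input = nrow(cells), kept = sum(keep),
                     low_rna = sum(cells$n_rna < min_rna),
                     low_dna = sum(cells$n_dna < min_dna)))
}

#' Library-size log-normalization
#'
#' `x -> ln(1 + scale * x / library_size)` per cell (column), the standard
#' log-normalization for single-cell counts.
#'
#' @param counts Genes x cells numeric matrix of raw counts.
#' @param scale Scale factor.
#' @return Matrix of the same shape.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  libsize <- colSums(counts)
  libsize[libsize == 0] <- 1
  log1p(sweep(counts, 2, libsize, "/") * scale)
}

#' Assign cell types to clusters from marker genes
#'
#' Cluster-level score for type A: twice the mean normalized expression of
#' A's marker genes over the cluster's cells, plus the proportion of cells
#' in the cluster with at least one A marker expressed (raw count > 0). The
#' argmax wins; exact ties go to the lexicographically first type with a
#' warning.
#'
#' @param cluster_labels Tibble: `cell_id`, `cluster` (precomputed cluster
#'   labels; graph clustering itself is out of scope here).
#' @param markers Tibble: `cell_type`, `gene_id`.
#' @param counts Genes x cells raw count matrix (dimnames required).
#' @param normalized Optional pre-computed [lognormalize()] matrix.
#' @return Tibble: `cluster`, `cell_type`, `score`, plus per-type scores in
#'   a list column `scores`.
#' @export
assign_cell_types <- function(cluster_labels, markers, counts,
                              normalized = lognormalize(counts)) {
  types <- sort(unique(markers$cell_type))
  out <- lapply(split(cluster_labels$cell_id, cluster_labels$cluster),
                function(cells) {
    cells <- intersect(cells, colnames(counts))
    sc <- vapply(types, function(tp) {
      g <- intersect(markers$gene_id[markers$cell_type == tp],
                     rownames(counts))
      if (length(g) == 0) return(-Inf)  # empty marker list: ineligible
      mean_expr <- mean(normalized[g, cells, drop = FALSE])
      prop <- mean(colSums(counts[g, cells, drop = FALSE] > 0) > 0)
      2 * mean_expr + prop
    }, numeric(1))
    best <- which(sc == max(sc))
    if (length(best) > 1) {
      warning("cell-type score tie; taking lexicographically first of: ",
              paste(types[best], collapse = ", "))
      best <- best[1]
    }
    tibble(cell_type = types[best], score = sc[best], scores = list(sc))
  })
  dplyr::bind_rows(out, .id = "cluster")
}

#' LCS-erosion score of a distance profile
#'
#' From a per-cell log-binned distance profile, takes the ten bins with the
#' highest normalized frequency (ties resolved toward smaller distance) and
#' returns the median of their bin midpoints (geometric mean of the edges;
#' the median of ten values is the mean of the 5th and 6th order
#' statistics). Cells with fewer than ten non-empty bins use all of them and
#' are flagged low-confidence. Scores above `threshold` classify the cell as
#' LCS-eroded.
#'
#' @param profile A [logbin_profile()] tibble (one or many cells).
#' @param n_top Number of top bins.
#' @param threshold Erosion classification threshold in bp.
#' @return Tibble: `cell_id`, `lcs_score`, `lcs_class`
#'   ("eroded"/"preserved"), `low_confidence`.
#' @export
lcs_erosion <- function(profile, n_top = 10L, threshold = 3e5) {
  profile |>
    mutate(midpoint = sqrt(.data$s_lo * .data$s_hi)) |>
    group_by(.data$cell_id) |>
    arrange(dplyr::desc(.data$value), .data$midpoint, .by_group = TRUE) |>
    summarise(
      lcs_score = median(.data$midpoint[seq_len(min(n_top, n()))]),
      low_confidence = n() < n_top, .groups = "drop") |>
    mutate(lcs_class = if_else(.data$lcs_score > threshold,
                               "eroded", "preserved"))
}

#' Transcriptomic age of single cells
#'
#' Each ageing gene's direction (+1/-1) is the sign of the correlation
#' between its mean expression per sample and the samples' chronological
#' ages; its weight is the proportion of cells expressing it (raw count > 0)
#' times the direction. A cell's age is the dot product of its per-gene
#' expression z-scores (over cells) with the gene weights. Zero-variance
#' genes are skipped and counted.
#'
#' @param counts Genes x cells raw count matrix (dimnames required).
#' @param ageing_genes Character vector of gene ids (rows of `counts`).
#' @param sample_of Named character vector: cell id -> sample id.
#' @param sample_ages Named numeric vector: sample id -> chronological age
#'   (needs >= 2 distinct ages).
#' @param normalized Optional [lognormalize()] matrix used for the z-scores.
#' @return List: `ages` tibble (`cell_id`, `transcriptomic_age`), `weights`
#'   tibble per gene, `n_skipped`.
#' @export
transcriptomic_age <- function(counts, ageing_genes, sample_of, sample_ages,
                               normalized = lognormalize(counts)) {
  if (length(unique(sample_ages)) < 2) {
    stop("need at least two distinct chronological ages to sign directions")
  }
  genes <- intersect(ageing_genes, rownames(counts))
  cells <- colnames(counts)
  samples <- names(sample_ages)
  smpl <- sample_of[cells]
  dir <- vapply(genes, function(g) {
    per_sample <- vapply(samples, function(s)
      mean(normalized[g, cells[smpl == s], drop = TRUE]), numeric(1))
    r <- suppressWarnings(cor(per_sample, sample_ages))
    if (is.na(r)) 0 else sign(r)
  }, numeric(1))
  prop <- rowMeans(counts[genes, , drop = FALSE] > 0)
  w <- prop * dir
  z <- t(scale(t(normalized[genes, , drop = FALSE])))
  keep <- !is.na(z[, 1]) & dir != 0
  n_skipped <- sum(!keep)
  age <- as.numeric(crossprod(z[keep, , drop = FALSE], w[keep]))
  list(ages = tibble(cell_id = cells, transcriptomic_age = age),
       weights = tibble(gene_id = genes, direction = unname(dir),
                        prop_expressing = unname(prop),
                        weight = unname(w), skipped = unname(!keep)),
       n_skipped = n_skipped)
}

#' Genes associated with the LCS-erosion score
#'
#' Per gene: F-test of a univariate linear regression of expression on the
#' LCS-erosion score and the Spearman correlation between the two; a gene
#' passes when P < `p_cut`, F > `f_cut` and |rho| > `rho_cut`. Constant
#' genes are skipped.
#'
#' @param expr Genes x cells matrix (normalized expression).
#' @param scores Named numeric vector: cell id -> LCS-erosion score.
#' @param p_cut,f_cut,rho_cut Significance thresholds.
#' @return Tibble: `gene_id`, `F`, `p_value`, `rho`, `pass`.
#' @export
lcs_gene_assoc <- function(expr, scores, p_cut = 0.01, f_cut = 1,
                           rho_cut = 0.1) {
  s <- scores[colnames(expr)]
  res <- lapply(rownames(expr), function(g) {
    y <- expr[g, ]
    if (stats::sd(y) == 0) return(NULL)
    fit <- lm(y ~ s)
    fs <- summary(fit)$fstatistic
    p <- pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    rho <- suppressWarnings(cor(s, y, method = "spearman"))
    tibble(gene_id = g, F = unname(fs[1]), p_value = unname(p), rho = rho)
  })
  dplyr::bind_rows(res) |>
    mutate(pass = .data$p_value < p_cut & .data$F > f_cut &
             abs(.data$rho) > rho_cut)
}
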