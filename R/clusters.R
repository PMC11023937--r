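#' Assemble deduplicated reads into clusters
#'
#' A cluster is the set of reads sharing one cell-barcode triple plus the
#' complex barcode (GEM + I7); it proxies one crosslinked molecular complex.
#'
#' @param reads Deduplicated, uniquely mapped read tibble (columns `cb1`,
#'   `cb2`, `cb3`, `gem`, `i7`, `modality`, ...).
#' @return List: `reads` (input + `cell_id`, `cluster_key`), `clusters`
#'   (one row per cluster: key, cell, `n_dna`, `n_rna`, `size`, `type`,
#'   `singleton`), `cells` (roster with per-cell DNA/RNA totals).
#' @export
build_clusters <- function(reads) {
  reads <- reads |>
    mutate(cell_id = paste(.data$cb1, .data$cb2, .data$cb3, sep = "_"),
           cluster_key = paste(.data$cb1, .data$cb2, .data$cb3, .data$gem,
                               .data$i7, sep = "_"))
  clusters <- reads |>
    group_by(.data$cell_id, .data$cluster_key) |>
    summarise(n_dna = sum(.data$modality == "DNA"),
              n_rna = sum(.data$modality == "RNA"), .groups = "drop") |>
    mutate(size = .data$n_dna + .data$n_rna,
           type = cluster_type(.data$n_dna, .data$n_rna),
           singleton = .data$size == 1L)
  cells <- clusters |>
    group_by(.data$cell_id) |>
    summarise(n_clusters = n(), n_dna = sum(.data$n_dna),
              n_rna = sum(.data$n_rna), .groups = "drop")
  list(reads = reads, clusters = clusters, cells = cells)
}

cluster_type <- function(n_dna, n_rna) {
  dplyr::case_when(n_dna > 0 & n_rna > 0 ~ "RNA-DNA",
                   n_dna > 0 ~ "DNA-only",
                   n_rna > 0 ~ "RNA-only",
                   TRUE ~ NA_character_)
}

# all unordered index pairs of 1..k, vectorized
.pair_idx <- function(k) {
  if (k < 2) return(matrix(integer(0), nrow = 2))
  utils::combn(k, 2L)
}

#' Decompose clusters into size-normalized pairwise contacts
#'
#' Homotypic clusters (all-DNA or all-RNA) of size N yield all C(N, 2)
#' unordered pairs, each with weight 1/N (total (N-1)/2). Heterotypic
#' clusters with M RNA and N DNA reads yield all M x N RNA-DNA pairs, each
#' with weight 1/(M+N) (total MN/(M+N)). For `type = "dna_dna"` with
#' `dna_source = "all_clusters"`, DNA-DNA pairs are also drawn from RNA-DNA
#' clusters, each weighted by that cluster's own factor 1/(M+N).
#'
#' @param reads Clustered read tibble (from [build_clusters()]`$reads`) with
#'   mapping columns `chrom`, `pos5`, `strand`.
#' @param type "dna_dna", "rna_dna" or "rna_rna".
#' @param dna_source For "dna_dna": "all_clusters" (default; DNA pairs from
#'   DNA-only and RNA-DNA clusters) or "dna_only_clusters".
#' @param region Optional `list(chrom =, start =, end =)` (0-based half-open);
#'   cluster membership and size are recomputed on region-restricted reads.
#' @param max_cluster_size Clusters larger than this (after restriction) are
#'   excluded.
#' @param rna_selector Optional predicate on the RNA reads (a function of the
#'   read tibble returning a logical); for "rna_dna", M counts selected RNA
#'   reads only and pairs use only those.
#' @return WeightedContact tibble: `cell_id`, `cluster_key`, ends A/B
#'   (`chrom_a`, `pos_a`, `strand_a`, `modality_a`, same for B), `weight`,
#'   `cluster_size` (the size used for the weight).
#' @export
decompose_contacts <- function(reads, type = c("dna_dna", "rna_dna", "rna_rna"),
                               dna_source = c("all_clusters", "dna_only_clusters"),
                               region = NULL, max_cluster_size = Inf,
                               rna_selector = NULL) {
  type <- match.arg(type)
  dna_source <- match.arg(dna_source)
  if (!is.null(region)) {
    reads <- reads |>
      filter(.data$chrom == region$chrom, .data$pos5 >= region$start,
             .data$pos5 < region$end)
  }
  if (!"cluster_key" %in% names(reads)) reads <- build_clusters(reads)$reads
  sel <- if (is.null(rna_selector)) {
    reads$modality == "RNA"
  } else {
    reads$modality == "RNA" & rna_selector(reads)
  }
  reads$.sel_rna <- sel
  parts <- split(seq_len(nrow(reads)), reads$cluster_key)
  out <- vector("list", length(parts))
  for (pi in seq_along(parts)) {
    idx <- parts[[pi]]
    m_all <- sum(reads$modality[idx] == "RNA")
    n_dna <- length(idx) - m_all
    size <- length(idx)
    if (size < 2 || size > max_cluster_size) next
    if (type == "dna_dna") {
      if (n_dna < 2) next
      if (dna_source == "dna_only_clusters" && m_all > 0) next
      w <- 1 / size   # = 1/N for DNA-only, 1/(M+N) for mixed clusters
      di <- idx[reads$modality[idx] == "DNA"]
      pr <- .pair_idx(length(di))
      a <- di[pr[1, ]]; b <- di[pr[2, ]]
    } else if (type == "rna_rna") {
      if (m_all != size || m_all < 2) next  # homotypic RNA clusters only
      w <- 1 / size
      ri <- idx
      pr <- .pair_idx(length(ri))
      a <- ri[pr[1, ]]; b <- ri[pr[2, ]]
    } else {
      mi <- idx[reads$.sel_rna[idx]]
      di <- idx[reads$modality[idx] == "DNA"]
      if (length(mi) == 0 || length(di) == 0) next
      w <- 1 / size
      g <- expand.grid(a = mi, b = di)
      a <- g$a; b <- g$b
    }
    out[[pi]] <- tibble(
      cell_id = reads$cell_id[a], cluster_key = reads$cluster_key[a],
      chrom_a = reads$chrom[a], pos_a = reads$pos5[a],
      strand_a = reads$strand[a], modality_a = reads$modality[a],
      chrom_b = reads$chrom[b], pos_b = reads$pos5[b],
      strand_b = reads$strand[b], modality_b = reads$modality[b],
      weight = w, cluster_size = size)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(cell_id = character(0), cluster_key = character(0),
                  chrom_a = character(0), pos_a = integer(0),
                  strand_a = character(0), modality_a = character(0),
                  chrom_b = character(0), pos_b = integer(0),
                  strand_b = character(0), modality_b = character(0),
                  weight = numeric(0), cluster_size = integer(0))
  }
  res
}

#' Decompose a single cluster
#'
#' @param members Tibble of one cluster's member reads (columns as in
#'   [decompose_contacts()]; a `cluster_key` is synthesized if absent).
#' @param ... Passed to [decompose_contacts()].
#' @return WeightedContact tibble (empty for singletons).
#' @export
decompose_cluster <- function(members, ...) {
  if (!"cluster_key" %in% names(members)) members$cluster_key <- "c1"
  if (!"cell_id" %in% names(members)) members$cell_id <- "cell1"
  decompose_contacts(members, ...)
}

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Cluster census by type and size class
#'
#' Counts clusters and reads by cluster type and size class (singleton, 2,
#' 3-10, >10) and reports percentages among non-singleton clusters of each
#' type (half-up rounding to 2 decimals). The derived ">=3" (multiplex)
#' class is included for DNA-only clusters.
#'
#' @param clusters Tibble with `n_dna`, `n_rna` and optionally `n` (the
#'   number of clusters this row stands for, so printed count tables can be
#'   fed directly).
#' @return A `music_census`: list with `by_class` tibble (`type`,
#'   `size_class`, `n_clusters`, `n_reads`, `pct`), `totals` tibble and
#'   `multiplex` tibble (pairwise vs >=3 for each type).
#' @export
census <- function(clusters) {
  if (nrow(clusters) == 0) {
    return(structure(list(by_class = tibble(), totals = tibble(),
                          multiplex = tibble()), class = "music_census"))
  }
  cl <- clusters
  if (!"n" %in% names(cl)) cl$n <- 1L
  cl <- cl |>
    mutate(size = .data$n_dna + .data$n_rna,
           type = cluster_type(.data$n_dna, .data$n_rna),
           size_class = dplyr::case_when(
             .data$size == 1 ~ "singleton",
             .data$size == 2 ~ "2",
             .data$size <= 10 ~ "3-10",
             TRUE ~ ">10"))
  by_class <- cl |>
    group_by(.data$type, .data$size_class) |>
    summarise(n_clusters = sum(.data$n),
              n_reads = sum(.data$n * .data$size), .groups = "drop")
  nonsing <- cl |> filter(.data$size > 1) |>
    group_by(.data$type) |>
    summarise(total = sum(.data$n), .groups = "drop")
  by_class <- by_class |>
    left_join(nonsing, by = "type") |>
    mutate(pct = if_else(.data$size_class == "singleton", NA_real_,
                         round_half_up(100 * .data$n_clusters / .data$total))) |>
    select(-"total")
  multiplex <- cl |> filter(.data$size > 1) |>
    mutate(class = if_else(.data$size == 2, "pairwise", "multiplex")) |>
    group_by(.data$type, .data$class) |>
    summarise(n_clusters = sum(.data$n), .groups = "drop") |>
    left_join(nonsing, by = "type") |>
    mutate(pct = round_half_up(100 * .data$n_clusters / .data$total)) |>
    select(-"total")
  totals <- cl |>
    group_by(.data$type) |>
    summarise(n_clusters = sum(.data$n),
              n_reads = sum(.data$n * .data$size),
              n_nonsingleton = sum(.data$n[.data$size > 1]),
              .groups = "drop")
  structure(list(by_class = by_class, totals = totals, multiplex = multiplex),
            class = "music_census")
}

#' @export
print.music_census <- function(x, ...) {
  cat("Cluster census\n")
  print(x$totals)
  print(x$multiplex)
  invisible(x)
}

#' Species-mixing quality control
#'
#' Cells with fewer than `ambient_threshold` DNA reads are called ambient;
#' otherwise a cell is assigned to a species when at least `cell_purity` of
#' its DNA reads map to that species, else called mixed. A cluster is
#' assigned to a species when more than `cluster_purity` of its uniquely
#' mapped non-duplicated DNA reads come from it.
#'
#' @param reads Clustered read tibble with `species` and `modality`.
#' @param cell_purity,cluster_purity,ambient_threshold QC thresholds.
#' @return List: `cells` (cell_id, n_dna, call), `clusters` (cluster_key,
#'   call), `mixing_rate` (fraction of non-ambient cells called mixed).
#' @export
species_qc <- function(reads, cell_purity = 0.95, cluster_purity = 0.99,
                       ambient_threshold = 1000L) {
  dna <- reads |> filter(.data$modality == "DNA", !is.na(.data$species))
  cell_tab <- dna |>
    count(.data$cell_id, .data$species) |>
    group_by(.data$cell_id) |>
    summarise(n_dna = sum(.data$n),
              top_species = .data$species[which.max(.data$n)],
              top_frac = max(.data$n) / sum(.data$n), .groups = "drop") |>
    mutate(call = dplyr::case_when(
      .data$n_dna < ambient_threshold ~ "ambient",
      .data$top_frac >= cell_purity ~ .data$top_species,
      TRUE ~ "mixed"))
  clust_tab <- dna |>
    count(.data$cluster_key, .data$species) |>
    group_by(.data$cluster_key) |>
    summarise(top_species = .data$species[which.max(.data$n)],
              top_frac = max(.data$n) / sum(.data$n), .groups = "drop") |>
    mutate(call = if_else(.data$top_frac > cluster_purity,
                          .data$top_species, "mixed"))
  non_ambient <- cell_tab |> filter(.data$call != "ambient")
  list(cells = cell_tab, clusters = clust_tab,
       mixing_rate = if (nrow(non_ambient)) {
         mean(non_ambient$call == "mixed")
       } else NA_real_)
}
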