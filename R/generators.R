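#' Simulate weighted contacts with a power-law distance distribution
#'
#' Emits size-2 cluster contacts (weight 1/2 each) with genomic distances
#' drawn from `p(s) ~ s^-alpha` on `[s_min, s_max]`; used to check that the
#' distance-decay machinery recovers a planted exponent.
#'
#' @param n_pairs Number of pairs.
#' @param alpha Planted exponent.
#' @param s_min,s_max Distance support in bp.
#' @param n_cells Pairs are spread uniformly over this many cells.
#' @param chrom Chromosome label.
#' @param seed Integer seed.
#' @return WeightedContact tibble compatible with [pc_curve()].
#' @export
simulate_powerlaw_contacts <- function(n_pairs, alpha = 1.0, s_min = 1e3,
                                       s_max = 1e8, n_cells = 100L,
                                       chrom = "chr1", seed = 1L) {
  withr_seed(seed)
  d <- round(rpower_law(n_pairs, alpha, s_min, s_max))
  pos_a <- floor(runif(n_pairs, 0, 2.4e8 - s_max))
  tibble(
    cell_id = sprintf("C%04d", sample.int(n_cells, n_pairs, replace = TRUE)),
    cluster_key = sprintf("K%07d", seq_len(n_pairs)),
    chrom_a = chrom, pos_a = pos_a, strand_a = "+", modality_a = "DNA",
    chrom_b = chrom, pos_b = pos_a + d, strand_b = "+", modality_b = "DNA",
    weight = 0.5, cluster_size = 2L)
}

#' Simulate a two-population mixture of per-cell contact profiles
#'
#' Plants "LCS-preserved" cells whose intrachromosomal contact distances are
#' log10-normal around `mu_log10["preserved"]` and "LCS-eroded" cells around
#' `mu_log10["eroded"]`; the separation straddles the 3e5-bp classification
#' threshold.
#'
#' @param n_cells Number of cells (split evenly, preserved first).
#' @param contacts_per_cell Pairs per cell.
#' @param mu_log10 Named centers (log10 bp) of the two populations.
#' @param sigma_log10 Common log10 spread.
#' @param eroded_fraction Fraction of eroded cells.
#' @param seed Integer seed.
#' @return List: `contacts` (WeightedContact tibble), `truth` tibble
#'   (`cell_id`, `true_class`).
#' @export
simulate_lcs_population <- function(n_cells = 200L, contacts_per_cell = 200L,
                                    mu_log10 = c(preserved = 4.5, eroded = 6.5),
                                    sigma_log10 = 0.4,
                                    eroded_fraction = 0.5, seed = 1L) {
  withr_seed(seed)
  n_eroded <- round(n_cells * eroded_fraction)
  truth <- tibble(
    cell_id = sprintf("C%04d", seq_len(n_cells)),
    true_class = rep(c("preserved", "eroded"),
                     c(n_cells - n_eroded, n_eroded)))
  n_tot <- n_cells * contacts_per_cell
  cls <- rep(truth$true_class, each = contacts_per_cell)
  d <- round(pmin(pmax(
    10^rnorm(n_tot, mu_log10[cls], sigma_log10), 5e3), 1.4e8))
  pos_a <- floor(runif(n_tot, 0, 2.4e8 - 1.5e8))
  contacts <- tibble(
    cell_id = rep(truth$cell_id, each = contacts_per_cell),
    cluster_key = sprintf("K%07d", seq_len(n_tot)),
    chrom_a = "chr1", pos_a = pos_a, strand_a = "+", modality_a = "DNA",
    chrom_b = "chr1", pos_b = pos_a + d, strand_b = "+", modality_b = "DNA",
    weight = 0.5, cluster_size = 2L)
  list(contacts = contacts, truth = truth)
}

#' Simulate ageing-modulated expression counts
#'
#' Cells carry a latent ageing factor in [0, 1] tied to their donor's
#' chronological age; each ageing gene's Poisson mean is modulated
#' `fold`-fold across the factor range in its planted direction. Non-ageing
#' background genes are flat.
#'
#' @param n_cells,n_ageing_genes,n_background_genes Problem sizes.
#' @param fold Expression modulation across the full factor range.
#' @param base_mean Baseline Poisson mean.
#' @param sample_ages Donor ages (cells split evenly; the factor's mean
#'   increases with donor age).
#' @param noise_sd Spread of the per-cell factor around its donor mean.
#' @param seed Integer seed.
#' @return List: `counts` (genes x cells), `ageing_genes`, `directions`,
#'   `sample_of`, `sample_ages`, `truth` tibble (`cell_id`, `ageing_factor`).
#' @export
simulate_ageing_expression <- function(n_cells = 500L, n_ageing_genes = 50L,
                                       n_background_genes = 50L, fold = 2,
                                       base_mean = 10,
                                       sample_ages = c(S1 = 62, S2 = 71,
                                                       S3 = 80, S4 = 89),
                                       noise_sd = 0.15, seed = 1L) {
  withr_seed(seed)
  cells <- sprintf("C%04d", seq_len(n_cells))
  smpl <- rep(names(sample_ages), length.out = n_cells)
  base_f <- (sample_ages[smpl] - min(sample_ages)) /
    diff(range(sample_ages))
  factor_i <- pmin(pmax(base_f + rnorm(n_cells, 0, noise_sd), 0), 1)
  genes_a <- sprintf("AGE%03d", seq_len(n_ageing_genes))
  genes_b <- sprintf("BG%03d", seq_len(n_background_genes))
  dirs <- stats::setNames(sample(c(-1, 1), n_ageing_genes, replace = TRUE),
                          genes_a)
  lam_a <- outer(dirs, factor_i - 0.5, function(d, f)
    base_mean * fold^(d * f))
  lam_b <- matrix(base_mean, n_background_genes, n_cells)
  counts <- rbind(
    matrix(rpois(length(lam_a), lam_a), nrow = n_ageing_genes),
    matrix(rpois(length(lam_b), lam_b), nrow = n_background_genes))
  dimnames(counts) <- list(c(genes_a, genes_b), cells)
  list(counts = counts, ageing_genes = genes_a, directions = dirs,
       sample_of = stats::setNames(smpl, cells),
       sample_ages = sample_ages,
       truth = tibble(cell_id = cells, ageing_factor = unname(factor_i)))
}

#' Simulate block-structured (TAD-like) multiplex clusters
#'
#' Emulates the regime in which self-interacting blocks (TADs) are built
#' from multiplex complexes: multiplex clusters place their members within
#' one planted genomic block (with a small uniform leak), while pairwise
#' clusters follow a plain distance-decay law that ignores block
#' boundaries. The qualitative expectation is that the size >= 3 contact
#' map concentrates more mass within blocks than the size-2 map.
#'
#' @param n_clusters Clusters per regime.
#' @param block_size,n_blocks Block geometry in bp / count.
#' @param multiplex_size Size of the multiplex clusters.
#' @param noise_frac Fraction of multiplex members placed uniformly.
#' @param pair_alpha Distance-law exponent for the pairwise regime.
#' @param seed Integer seed.
#' @return Tibble of clustered reads (columns as for
#'   [decompose_contacts()]).
#' @export
simulate_tad_clusters <- function(n_clusters = 400L, block_size = 1e6,
                                  n_blocks = 10L, multiplex_size = 6L,
                                  noise_frac = 0.1, pair_alpha = 0.9,
                                  seed = 1L) {
  withr_seed(seed)
  L <- n_blocks * block_size
  # multiplex: block-confined
  multi <- purrr::map_dfr(seq_len(n_clusters), function(i) {
    blk <- sample.int(n_blocks, 1L)
    pos <- floor(runif(multiplex_size, (blk - 1) * block_size,
                       blk * block_size))
    unif <- runif(multiplex_size) < noise_frac
    pos[unif] <- floor(runif(sum(unif), 0, L))
    tibble(cell_id = "C0001", cluster_key = sprintf("M%05d", i),
           modality = "DNA", chrom = "chr1", pos5 = as.integer(pos),
           strand = "+")
  })
  # pairwise: block-ignorant distance decay
  a <- floor(runif(n_clusters, 0, L))
  d <- round(rpower_law(n_clusters, pair_alpha, 1e3, 5e6)) *
    sample(c(-1L, 1L), n_clusters, replace = TRUE)
  b <- pmin(pmax(a + d, 0), L - 1)
  pair <- tibble(
    cell_id = "C0001",
    cluster_key = rep(sprintf("P%05d", seq_len(n_clusters)), 2L),
    modality = "DNA", chrom = "chr1",
    pos5 = as.integer(c(a, b)), strand = "+")
  dplyr::bind_rows(pair, multi)
}
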