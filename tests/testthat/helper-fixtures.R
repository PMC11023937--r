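# Shared desk-scale fixtures, built once per test run.
.fx <- new.env()

fx_ref <- function() {
  if (is.null(.fx$ref)) {
    .fx$ref <- make_reference(
      reference_config(species = list(human = c(chr1 = 2e5, chrX = 1.5e5)),
                       n_genes = 15L),
      seed = 11)
  }
  .fx$ref
}

fx_tables <- function() {
  if (is.null(.fx$tables)) .fx$tables <- music_barcode_tables(seed = 13)
  .fx$tables
}

fx_index <- function() {
  if (is.null(.fx$index)) .fx$index <- build_index(fx_ref())
  .fx$index
}

# zero-noise mini dataset: 30 cells, ground truth + emitted records + pipeline
fx_run <- function() {
  if (is.null(.fx$run)) {
    gt <- simulate_ground_truth(
      fx_ref(),
      sim_config(n_cells = 30L, complexes_per_cell = 12L, d_max = 5e4,
                 xist_rate = 0.3),
      seed = 17, tables = fx_tables())
    em <- emit_reads(gt, seed = 17)
    pp <- run_pipeline(em$records, fx_tables(), fx_index())
    .fx$run <- list(gt = gt, em = em, pp = pp)
  }
  .fx$run
}

# cluster-read tibble builder for decomposition tests
make_cluster_reads <- function(n_dna, n_rna, cluster_key = "k1",
                               cell_id = "c1", chrom = "chr1",
                               pos = NULL, gene_id = NULL) {
  n <- n_dna + n_rna
  if (is.null(pos)) pos <- seq(1e4, by = 1e4, length.out = n)
  tibble::tibble(
    cell_id = cell_id, cluster_key = cluster_key,
    modality = rep(c("RNA", "DNA"), c(n_rna, n_dna)),
    chrom = chrom, pos5 = as.integer(pos), strand = "+",
    gene_id = if (is.null(gene_id)) {
      c(rep("G00001", n_rna), rep(NA_character_, n_dna))
    } else gene_id)
}
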