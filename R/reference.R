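#' Configuration for a synthetic reference genome
#'
#' Desk-scale stand-in for a real genome + annotation: one or more species,
#' each with a few random-sequence chromosomes, an annotated gene set with
#' exon/intron structure, an XIST-like lncRNA on the X chromosome, per-type
#' marker genes and direction-labelled ageing genes.
#'
#' @param species Named list; each element is a named numeric vector of
#'   chromosome lengths (names are chromosome names; a name containing "X"
#'   marks the X chromosome).
#' @param n_genes Genes to place per chromosome (best effort; placement stops
#'   at the chromosome end).
#' @param gene_length Integer range (min, max) of gene lengths in bp.
#' @param arm_fraction Position of the arm boundary as a fraction of the
#'   chromosome length.
#' @param cell_types Cell-type labels used for marker-gene sets.
#' @param markers_per_type,n_ageing_genes Sizes of the planted gene sets.
#' @return A plain list of class `reference_config`.
#' @export
reference_config <- function(species = list(human = c(chr1 = 6e5, chr2 = 5e5, chrX = 5e5)),
                             n_genes = 40L,
                             gene_length = c(2000L, 6000L),
                             arm_fraction = 0.45,
                             cell_types = c("Ast", "ExN", "InN", "Mic", "Oli", "Opc"),
                             markers_per_type = 5L,
                             n_ageing_genes = 50L) {
  structure(as.list(environment()), class = "reference_config")
}

#' Build a synthetic reference
#'
#' Deterministic for a given `(config, seed)`. Chromosome names are prefixed
#' with the species id when more than one species is configured, so a
#' mixed-species index never shares chromosome names.
#'
#' @param config A [reference_config()].
#' @param seed Integer seed.
#' @return A `music_reference` list: `seqs` (a [Biostrings::DNAStringSet]),
#'   `chromosomes`, `genes`, `exons` tibbles (1-based inclusive coordinates,
#'   GTF convention) and `gene_sets` (markers, ageing, xist).
#' @export
#' @examples
#' ref <- make_reference(reference_config(), seed = 7)
#' ref$chromosomes
make_reference <- function(config = reference_config(), seed = 1L) {
  stopifnot(inherits(config, "reference_config"))
  if (max(config$gene_length) > min(unlist(config$species))) {
    stop("configuration error: a chromosome is shorter than the largest requested gene")
  }
  withr_seed(seed)
  multi <- length(config$species) > 1L
  chroms <- purrr::imap_dfr(config$species, function(lens, sp) {
    nm <- if (multi) paste0(sp, "_", names(lens)) else names(lens)
    tibble(species = sp, chrom = nm, length = as.integer(lens),
           arm_boundary = as.integer(round(lens * config$arm_fraction)),
           is_x = grepl("X", names(lens)))
  })
  seqs <- Biostrings::DNAStringSet(vapply(chroms$length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  names(seqs) <- chroms$chrom

  gl <- config$gene_length
  genes_l <- list(); exons_l <- list()
  gid <- 0L
  for (ci in seq_len(nrow(chroms))) {
    pos <- 1000L
    placed <- 0L
    while (placed < config$n_genes) {
      len <- sample(gl[1]:gl[2], 1L)
      if (pos + len + 1000L > chroms$length[ci]) break
      gid <- gid + 1L; placed <- placed + 1L
      id <- sprintf("G%05d", gid)
      strand <- sample(c("+", "-"), 1L)
      biotype <- sample(c("protein_coding", "lincRNA"), 1L, prob = c(0.85, 0.15))
      n_ex <- sample(1:3, 1L)
      genes_l[[gid]] <- tibble(
        gene_id = id, gene_name = id, species = chroms$species[ci],
        chrom = chroms$chrom[ci], start = pos, end = pos + len - 1L,
        strand = strand, biotype = biotype, xist_like = FALSE)
      # split the gene body into alternating exon/intron blocks
      if (n_ex == 1L) {
        exons_l[[length(exons_l) + 1L]] <- tibble(
          gene_id = id, exon_number = 1L, start = pos, end = pos + len - 1L)
      } else {
        cuts <- sort(sample(seq(200L, len - 200L, by = 50L), 2L * (n_ex - 1L)))
        bounds <- c(0L, cuts, len)
        blocks <- tibble(start = pos + bounds[-length(bounds)],
                         end = pos + bounds[-1] - 1L)
        ex <- blocks[seq(1, nrow(blocks), by = 2), ]
        exons_l[[length(exons_l) + 1L]] <- tibble(
          gene_id = id, exon_number = seq_len(nrow(ex)),
          start = ex$start, end = ex$end)
      }
      pos <- pos + len + sample(500:3000, 1L)
    }
  }
  genes <- dplyr::bind_rows(genes_l)
  exons <- dplyr::bind_rows(exons_l)

  # one XIST-like single-exon lncRNA per X chromosome
  for (xc in chroms$chrom[chroms$is_x]) {
    gid <- gid + 1L
    xlen <- 4000L
    xstart <- as.integer(chroms$length[chroms$chrom == xc] - xlen - 500L)
    sp <- chroms$species[chroms$chrom == xc]
    genes <- dplyr::bind_rows(genes, tibble(
      gene_id = "XIST_LIKE", gene_name = "XIST_LIKE", species = sp,
      chrom = xc, start = xstart, end = xstart + xlen - 1L,
      strand = "+", biotype = "lncRNA", xist_like = TRUE))
    exons <- dplyr::bind_rows(exons, tibble(
      gene_id = "XIST_LIKE", exon_number = 1L,
      start = xstart, end = xstart + xlen - 1L))
  }

  pc <- genes$gene_id[genes$biotype == "protein_coding"]
  nmark <- length(config$cell_types) * config$markers_per_type
  pick <- sample(pc, min(length(pc), nmark + config$n_ageing_genes))
  n_mark_use <- min(nmark, length(pick))
  markers <- tibble(
    cell_type = rep(config$cell_types,
                    each = config$markers_per_type)[seq_len(n_mark_use)],
    gene_id = pick[seq_len(n_mark_use)])
  n_age_use <- max(0L, min(config$n_ageing_genes, length(pick) - n_mark_use))
  ageing <- tibble(gene_id = pick[n_mark_use + seq_len(n_age_use)])
  ageing$direction <- sample(c(-1L, 1L), nrow(ageing), replace = TRUE)

  structure(list(seqs = seqs, chromosomes = chroms, genes = genes,
                 exons = exons,
                 gene_sets = list(markers = markers, ageing = ageing,
                                  xist = "XIST_LIKE"),
                 config = config, seed = seed),
            class = "music_reference")
}

#' Write a reference as FASTA + GTF
#'
#' @param ref A `music_reference`.
#' @param dir Output directory; writes `genome.fa` and `genes.gtf`.
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$seqs, file.path(dir, "genome.fa"))
  rtracklayer::export(reference_gtf(ref), file.path(dir, "genes.gtf"),
                      format = "gtf")
  invisible(dir)
}

#' Annotation of a reference as a GRanges (GTF-shaped)
#'
#' @param ref A `music_reference`.
#' @return A [GenomicRanges::GRanges] with `type` gene/exon rows and
#'   `gene_id`, `gene_biotype`, `xist_like` attributes.
#' @export
reference_gtf <- function(ref) {
  g <- ref$genes
  e <- dplyr::left_join(ref$exons,
                        dplyr::select(g, "gene_id", "chrom", "strand",
                                      "biotype", "xist_like"),
                        by = "gene_id")
  gr_g <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", gene_id = g$gene_id, gene_name = g$gene_name,
    gene_biotype = g$biotype, xist_like = tolower(as.character(g$xist_like)))
  gr_e <- GenomicRanges::GRanges(
    e$chrom, IRanges::IRanges(e$start, e$end), strand = e$strand,
    type = "exon", gene_id = e$gene_id, gene_name = e$gene_id,
    gene_biotype = e$biotype, xist_like = tolower(as.character(e$xist_like)))
  sl <- stats::setNames(ref$chromosomes$length, ref$chromosomes$chrom)
  gr <- c(gr_g, gr_e)
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  gr
}

#' Intron intervals of a reference
#'
#' Gaps between consecutive exons within each gene body.
#'
#' @param ref A `music_reference`.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `biotype`, `start`, `end`
#'   (1-based inclusive).
#' @export
reference_introns <- function(ref) {
  ref$exons |>
    dplyr::left_join(dplyr::select(ref$genes, "gene_id", "chrom", "strand",
                                   "biotype"), by = "gene_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::reframe(chrom = .data$chrom[-1], strand = .data$strand[-1],
                   biotype = .data$biotype[-1],
                   start = utils::head(.data$end, -1) + 1L,
                   end = .data$start[-1] - 1L) |>
    dplyr::filter(.data$end >= .data$start)
}

#' Gene-density track over a bin scheme
#'
#' Counts gene bases per bin; used as the orientation reference for
#' compartment (PC1) scores, mirroring the convention that the A compartment
#' is gene dense.
#'
#' @param ref A `music_reference`.
#' @param chrom Chromosome name.
#' @param resolution Bin width in bp.
#' @return Numeric vector, one value per bin.
#' @export
gene_density_track <- function(ref, chrom, resolution) {
  L <- ref$chromosomes$length[ref$chromosomes$chrom == chrom]
  n_bins <- ceiling(L / resolution)
  dens <- numeric(n_bins)
  g <- ref$genes[ref$genes$chrom == chrom, ]
  for (i in seq_len(nrow(g))) {
    bins <- seq(((g$start[i] - 1) %/% resolution) + 1,
                ((g$end[i] - 1) %/% resolution) + 1)
    dens[bins] <- dens[bins] + 1
  }
  dens
}
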