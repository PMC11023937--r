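#' Annotate RNA reads against the gene annotation
#'
#' Strand-aware classification: `pre-mRNA` requires at least
#' `min_intron_overlap` bp of same-strand overlap with an intron of a
#' protein-coding gene; otherwise `exonic` for same-strand exon overlap,
#' otherwise `intergenic`. A gene id is assigned from the overlapped feature
#' (largest same-strand gene-body overlap).
#'
#' @param reads RNA read tibble with `chrom`, `start` (0-based), `strand` and
#'   `insert` (or `length`).
#' @param ref A [make_reference()] object (the GTF-shaped annotation source).
#' @param min_intron_overlap Minimum intron overlap in bp for the pre-mRNA
#'   call.
#' @return Input tibble + `rna_class` and `gene_id` columns.
#' @export
annotate_rna_reads <- function(reads, ref, min_intron_overlap = 15L) {
  len <- if ("insert" %in% names(reads)) nchar(reads$insert) else reads$length
  gr <- GenomicRanges::GRanges(reads$chrom,
                               IRanges::IRanges(reads$start + 1L,
                                                width = len),
                               strand = reads$strand)
  genes <- ref$genes
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end),
                                     strand = genes$strand)
  introns <- reference_introns(ref)
  out <- reads
  out$gene_id <- NA_character_
  out$rna_class <- "intergenic"

  hits <- GenomicRanges::findOverlaps(gr, gr_genes, ignore.strand = FALSE)
  if (length(hits) > 0) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(gr_genes)[S4Vectors::subjectHits(hits)]))
    best <- tibble(q = S4Vectors::queryHits(hits),
                   s = S4Vectors::subjectHits(hits), ov = ov) |>
      group_by(.data$q) |>
      dplyr::slice_max(.data$ov, n = 1, with_ties = FALSE) |>
      ungroup()
    out$gene_id[best$q] <- genes$gene_id[best$s]
  }

  exons <- dplyr::left_join(ref$exons,
                            dplyr::select(genes, "gene_id", "chrom", "strand"),
                            by = "gene_id")
  gr_ex <- GenomicRanges::GRanges(exons$chrom,
                                  IRanges::IRanges(exons$start, exons$end),
                                  strand = exons$strand)
  ex_hit <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(gr, gr_ex, ignore.strand = FALSE)))
  out$rna_class[ex_hit] <- "exonic"

  if (nrow(introns) > 0) {
    pc_introns <- introns[introns$biotype == "protein_coding", ]
    if (nrow(pc_introns) > 0) {
      gr_in <- GenomicRanges::GRanges(
        pc_introns$chrom,
        IRanges::IRanges(pc_introns$start, pc_introns$end),
        strand = pc_introns$strand)
      ih <- GenomicRanges::findOverlaps(gr, gr_in, ignore.strand = FALSE,
                                        minoverlap = min_intron_overlap)
      pre <- unique(S4Vectors::queryHits(ih))
      out$rna_class[pre] <- "pre-mRNA"
    }
  }
  out
}

#' Gene-level RNA quantification
#'
#' Reads per kilobase of gene length, from annotated RNA reads.
#'
#' @param annotated Output of [annotate_rna_reads()].
#' @param ref A [make_reference()] object.
#' @return Tibble: `gene_id`, `n_reads`, `rpk`.
#' @export
quantify_rna <- function(annotated, ref) {
  annotated |>
    filter(!is.na(.data$gene_id)) |>
    count(.data$gene_id, name = "n_reads") |>
    left_join(dplyr::transmute(ref$genes, gene_id = .data$gene_id,
                               kb = (.data$end - .data$start + 1) / 1000),
              by = "gene_id") |>
    mutate(rpk = .data$n_reads / .data$kb) |>
    select("gene_id", "n_reads", "rpk")
}

#' RNA attachment level (RAL) track
#'
#' For every cluster with at least one selected RNA read (and total size not
#' exceeding `max_cluster_size`), all selected-RNA x DNA pairs contribute
#' weight 1/(cluster size) at their DNA end's genomic bin; the track is the
#' per-bin total.
#'
#' @param reads Clustered, mapped read tibble with a `gene_id` column on RNA
#'   reads.
#' @param rna_selector Predicate on the read tibble selecting the RNA class
#'   of interest (e.g. XIST reads, a speckle gene set).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param resolution Bin width (default 1 Mb).
#' @param max_cluster_size Clusters above this size are excluded.
#' @return A `music_ral_track` tibble: `chrom`, `bin`, `start`, `end`, `ral`.
#' @export
ral_track <- function(reads, rna_selector, chrom_lengths, resolution = 1e6,
                      max_cluster_size = 1000L) {
  pairs <- decompose_contacts(reads, type = "rna_dna",
                              max_cluster_size = max_cluster_size,
                              rna_selector = rna_selector)
  out <- pairs |>
    mutate(bin = .data$pos_b %/% resolution + 1L) |>
    group_by(chrom = .data$chrom_b, bin = .data$bin) |>
    summarise(ral = sum(.data$weight), .groups = "drop") |>
    mutate(start = (.data$bin - 1L) * resolution,
           end = pmin(.data$bin * resolution, chrom_lengths[.data$chrom])) |>
    select("chrom", "bin", "start", "end", "ral")
  structure(out, class = c("music_ral_track", class(out)),
            resolution = resolution)
}

#' Two-dimensional RNA-DNA contact map for one chromosome
#'
#' `M[i, j]` is the summed weight of RNA-DNA pairs whose RNA end maps to bin
#' i and DNA end to bin j (not symmetric).
#'
#' @param reads Clustered, mapped read tibble.
#' @param chrom Chromosome name.
#' @param chrom_length Its length in bp.
#' @param resolution Bin width.
#' @param max_cluster_size Size cap applied after restriction to the
#'   chromosome.
#' @return List: `tbl` (sparse: `rna_bin`, `dna_bin`, `weight`), `n_bins`,
#'   `dense()` helper-free dense matrix.
#' @export
rna_dna_matrix <- function(reads, chrom, chrom_length, resolution = 1e6,
                           max_cluster_size = Inf) {
  pairs <- decompose_contacts(
    reads, type = "rna_dna",
    region = list(chrom = chrom, start = 0, end = chrom_length),
    max_cluster_size = max_cluster_size)
  tbl <- pairs |>
    mutate(rna_bin = .data$pos_a %/% resolution + 1L,
           dna_bin = .data$pos_b %/% resolution + 1L) |>
    group_by(.data$rna_bin, .data$dna_bin) |>
    summarise(weight = sum(.data$weight), .groups = "drop")
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  dense <- matrix(0, n_bins, n_bins)
  dense[cbind(tbl$rna_bin, tbl$dna_bin)] <- tbl$weight
  list(tbl = tbl, n_bins = n_bins, dense = dense)
}

#' Per-cell XIST-chromosome X association level (XAL)
#'
#' XAL is the number of distinct 1-Mb chromosome X bins with positive XIST
#' RAL in that cell; any positive attachment weight counts.
#'
#' @param reads Clustered, mapped read tibble with `gene_id` on RNA reads and
#'   `cell_id`.
#' @param chrx Chromosome X name.
#' @param chrx_length Its length in bp.
#' @param xist_genes Gene ids counted as XIST.
#' @param resolution Bin width.
#' @param max_cluster_size Cluster-size cap for the RAL weights.
#' @return Tibble: `cell_id`, `xal`, `n_xist_rna`, `n_chrx_dna`.
#' @export
xal <- function(reads, chrx, chrx_length, xist_genes = "XIST_LIKE",
                resolution = 1e6, max_cluster_size = 1000L) {
  sel <- function(r) !is.na(r$gene_id) & r$gene_id %in% xist_genes
  pairs <- decompose_contacts(reads, type = "rna_dna",
                              max_cluster_size = max_cluster_size,
                              rna_selector = sel) |>
    filter(.data$chrom_b == chrx)
  per_cell <- pairs |>
    mutate(bin = .data$pos_b %/% resolution + 1L) |>
    group_by(.data$cell_id) |>
    summarise(xal = dplyr::n_distinct(.data$bin), .groups = "drop")
  counts <- reads |>
    group_by(.data$cell_id) |>
    summarise(
      n_xist_rna = sum(.data$modality == "RNA" & !is.na(.data$gene_id) &
                         .data$gene_id %in% xist_genes),
      n_chrx_dna = sum(.data$modality == "DNA" & .data$chrom == chrx,
                       na.rm = TRUE),
      .groups = "drop")
  counts |>
    left_join(per_cell, by = "cell_id") |>
    mutate(xal = dplyr::coalesce(.data$xal, 0L)) |>
    select("cell_id", "xal", "n_xist_rna", "n_chrx_dna")
}

#' Stratify cells into four XAL groups
#'
#' Group "zero" holds cells with XAL 0; remaining cells are sorted by XAL
#' (ties broken by cell id for determinism) and cut into three equal-count
#' groups "low" < "medium" < "high" (sizes differ by at most 1).
#'
#' @param xal_records Output of [xal()].
#' @return Input + `group` factor.
#' @export
stratify_by_xal <- function(xal_records) {
  df <- arrange(xal_records, .data$xal, .data$cell_id)
  grp <- rep("zero", nrow(df))
  pos <- which(df$xal > 0)
  if (length(pos) > 0) {
    thirds <- cut(seq_along(pos), breaks = 3, labels = c("low", "medium", "high"))
    grp[pos] <- as.character(thirds)
  }
  df$group <- factor(grp, levels = c("zero", "low", "medium", "high"))
  df
}

#' Distance-decay curves for XIST-positive versus XIST-negative chromatin
#'
#' XIST+ clusters contain at least one XIST RNA read; XIST- clusters are
#' RNA-DNA and (by default) DNA-only clusters without any XIST read. Both
#' sets are decomposed into chromosome X DNA-DNA pairs and summarized as
#' [pc_curve()]s. `split = "any_rna"` gives the any-RNA+/- control split
#' instead.
#'
#' @param reads Clustered, mapped read tibble with `gene_id` on RNA reads.
#' @param chrx Chromosome X name.
#' @param xist_genes Gene ids counted as XIST.
#' @param split "xist" or "any_rna".
#' @param include_dna_only Whether DNA-only clusters enter the negative set.
#' @param ... Passed to [pc_curve()] (e.g. `n_bins`, `mode`).
#' @return List: `pos`, `neg` ([pc_curve()] objects; `NULL` when a set has
#'   no decomposable cluster).
#' @export
xist_split_pc <- function(reads, chrx, xist_genes = "XIST_LIKE",
                          split = c("xist", "any_rna"),
                          include_dna_only = TRUE, ...) {
  split <- match.arg(split)
  if (!"cluster_key" %in% names(reads)) reads <- build_clusters(reads)$reads
  flag <- if (split == "xist") {
    reads$modality == "RNA" & !is.na(reads$gene_id) &
      reads$gene_id %in% xist_genes
  } else {
    reads$modality == "RNA"
  }
  pos_keys <- unique(reads$cluster_key[flag])
  is_pos <- reads$cluster_key %in% pos_keys
  has_rna_keys <- unique(reads$cluster_key[reads$modality == "RNA"])
  neg <- reads[!is_pos, ]
  if (!include_dna_only) neg <- neg[neg$cluster_key %in% has_rna_keys, ]
  region <- list(chrom = chrx, start = 0, end = Inf)
  curve_of <- function(r) {
    cc <- decompose_contacts(r, type = "dna_dna",
                             dna_source = "all_clusters", region = region)
    if (nrow(cc) == 0) NULL else pc_curve(cc, ...)
  }
  list(pos = curve_of(reads[is_pos, ]), neg = curve_of(neg))
}
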