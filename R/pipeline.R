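#' Run the full read-processing pipeline
#'
#' demultiplex -> map -> deduplicate -> cluster, starting from in-memory
#' read records or a FASTQ triplet directory.
#'
#' @param records Tibble of read records (`read_id`, `r1`, `i1`, `r2`, `q2`)
#'   or a directory containing `R1.fastq.gz`, `I1.fastq.gz`, `R2.fastq.gz`.
#' @param tables A [music_barcode_tables()].
#' @param index A [build_index()] object.
#' @param layout A [music_layout()].
#' @return List: `demux` (parse result), `mapped`, `dedup` (retained reads),
#'   `n_duplicates`, `clusters` (from [build_clusters()]), `report`.
#' @export
run_pipeline <- function(records, tables, index, layout = music_layout()) {
  if (is.character(records)) {
    dmx <- demux_fastq(file.path(records, "R1.fastq.gz"),
                       file.path(records, "I1.fastq.gz"),
                       file.path(records, "R2.fastq.gz"), tables, layout)
  } else {
    dmx <- parse_read_pairs(records, tables, layout)
  }
  mapped <- map_reads(dmx$tagged, index)
  uniq <- mapped |>
    filter(.data$map_class == "unique") |>
    arrange(.data$chrom, .data$start)
  dd <- deduplicate(uniq)
  cl <- build_clusters(dd$reads)
  report <- c(dmx$report,
              list(mapped_unique = nrow(uniq),
                   mapped_multi = sum(mapped$map_class == "multi"),
                   unmapped = sum(mapped$map_class == "unmapped"),
                   duplicates_removed = dd$n_duplicates,
                   umndbc = nrow(dd$reads),
                   n_clusters = nrow(cl$clusters),
                   n_cells = nrow(cl$cells)))
  list(demux = dmx, mapped = mapped, dedup = dd$reads,
       n_duplicates = dd$n_duplicates, clusters = cl, report = report)
}
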