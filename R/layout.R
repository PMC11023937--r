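#' MUSIC read layout
#'
#' Describes how a MUSIC read triple is organized. R1 (28 bp) carries the 16-nt
#' droplet (GEM) barcode followed by the 12-nt GEM UMI; I1 (8 bp) is the I7
#' library index; R2 (150 bp) carries the third, second and first cell barcodes
#' (14 nt each, separated by configurable spacers), then the RNA or DNA linker
#' and finally the insert.
#'
#' The RNA linker reads as `CGAGGAG` + `CGCTT` + 5-nt UMI + `ATAGCATTGC`; the
#' DNA linker as `CGAGGAG` + 5-nt UMI + `ACAACGCACAGTGTCTAGT`. The two
#' signatures share only the `CGAGGAG` prefix, so modality is decided from the
#' bases that follow it.
#'
#' @param spacer1 Constant bases between the third and second cell barcode.
#' @param spacer2 Constant bases between the second and first cell barcode.
#' @param r2_length Total R2 read length in bases.
#' @return A `music_layout` list with barcode lengths, linker signatures and
#'   derived offsets.
#' @export
#' @examples
#' lay <- music_layout()
#' lay$linker_offset  # where the linker region starts within R2
music_layout <- function(spacer1 = "GGTGGTC", spacer2 = "CCTCCTA",
                         r2_length = 150L) {
  shared <- "CGAGGAG"
  rna_sig1 <- "CGCTT"
  rna_sig2 <- "ATAGCATTGC"
  dna_sig <- "ACAACGCACAGTGTCTAGT"
  cb_len <- 14L
  umi_len <- 5L
  prefix_len <- 3L * cb_len + nchar(spacer1) + nchar(spacer2)
  rna_linker_len <- nchar(shared) + nchar(rna_sig1) + umi_len + nchar(rna_sig2)
  dna_linker_len <- nchar(shared) + umi_len + nchar(dna_sig)
  lay <- structure(list(
    gem_len = 16L, gem_umi_len = 12L, i7_len = 8L,
    cb_len = cb_len, spacer1 = spacer1, spacer2 = spacer2,
    shared_prefix = shared, rna_sig1 = rna_sig1, rna_sig2 = rna_sig2,
    dna_sig = dna_sig, linker_umi_len = umi_len,
    r2_length = as.integer(r2_length),
    linker_offset = as.integer(prefix_len),
    rna_linker_len = as.integer(rna_linker_len),
    dna_linker_len = as.integer(dna_linker_len)
  ), class = "music_layout")
  validate_layout(lay)
  lay
}

validate_layout <- function(lay) {
  longest <- lay$linker_offset + max(lay$rna_linker_len, lay$dna_linker_len)
  if (longest >= lay$r2_length) {
    stop("R2 prefix (barcodes + linker) must be shorter than the R2 read: ",
         longest, " >= ", lay$r2_length)
  }
  # modality must be decidable: compare post-prefix signature bases, UMI
  # positions are wildcards
  rna <- strsplit(paste0(lay$rna_sig1, strrep("N", lay$linker_umi_len),
                         lay$rna_sig2), "")[[1]]
  dna <- strsplit(paste0(strrep("N", lay$linker_umi_len), lay$dna_sig), "")[[1]]
  L <- min(length(rna), length(dna))
  fixed <- rna[seq_len(L)] != "N" & dna[seq_len(L)] != "N"
  if (sum(rna[seq_len(L)][fixed] != dna[seq_len(L)][fixed]) < 5) {
    stop("RNA and DNA linker signatures differ at fewer than 5 fixed positions")
  }
  invisible(lay)
}

#' Number of distinct cell-barcode combinations
#'
#' Three rounds of split-pool ligation over whitelists of 96 barcodes each
#' address `96^3 = 884736` combinations.
#'
#' @param tables A `music_barcode_tables()` object (optional); defaults to the
#'   standard three 96-entry whitelists.
#' @return Integer count of distinct (cb1, cb2, cb3) combinations.
#' @export
barcode_space <- function(tables = NULL) {
  if (is.null(tables)) return(96L * 96L * 96L)
  as.integer(prod(vapply(tables[c("cb1", "cb2", "cb3")], length,
                         integer(1))))
}

# minimum Hamming distance from `cand` to each row of the accepted set
.hamming_to_set <- function(cand, set) {
  if (length(set) == 0L) return(Inf)
  cm <- strsplit(cand, "")[[1]]
  min(vapply(strsplit(set, ""), function(s) sum(s != cm), numeric(1)))
}

.gen_whitelist <- function(n, len, min_dist = 3L, seed_state_ok = TRUE) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    if (.hamming_to_set(cand, out) >= min_dist) out <- c(out, cand)
    tries <- tries + 1L
    if (tries > 200L * n) stop("whitelist generation failed to converge")
  }
  out
}

#' Generate synthetic barcode whitelists
#'
#' Builds the three 96-entry 14-nt cell-barcode whitelists, a GEM-barcode
#' whitelist and the 8-entry 8-nt I7 whitelist. Every whitelist is generated
#' with a minimum pairwise Hamming distance of 3, so a single substitution can
#' always be corrected unambiguously.
#'
#' @param n_gem Number of GEM barcodes to generate (the real assay draws from
#'   a 3.5-million oligo pool; a smaller pool suffices for simulation).
#' @param seed Integer seed; tables are deterministic given the seed.
#' @return A `music_barcode_tables` list with elements `cb1`, `cb2`, `cb3`,
#'   `gem`, `i7` (character vectors; ids are positions).
#' @export
music_barcode_tables <- function(n_gem = 4096L, seed = 1L) {
  withr_seed(seed)
  tabs <- structure(list(
    cb1 = .gen_whitelist(96L, 14L),
    cb2 = .gen_whitelist(96L, 14L),
    cb3 = .gen_whitelist(96L, 14L),
    gem = .gen_whitelist(as.integer(n_gem), 16L),
    i7  = .gen_whitelist(8L, 8L)
  ), class = "music_barcode_tables")
  tabs
}

# local seed that does not clobber the caller's RNG stream
withr_seed <- function(seed) {
  seed <- as.integer(seed %% .Machine$integer.max)
  set.seed(seed)
  invisible(seed)
}

#' Write / read barcode whitelists as TSV
#'
#' One file per whitelist, two columns (`id`, `sequence`), no header
#' compression; round-trips through [read_barcode_tables()].
#'
#' @param tables A `music_barcode_tables` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_barcode_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    df <- data.frame(id = seq_along(tables[[nm]]), sequence = tables[[nm]])
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_barcode_tables
#' @export
read_barcode_tables <- function(dir) {
  nms <- c("cb1", "cb2", "cb3", "gem", "i7")
  tabs <- lapply(nms, function(nm) {
    df <- utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                            header = TRUE, sep = "\t",
                            colClasses = c("integer", "character"))
    df$sequence[order(df$id)]
  })
  structure(stats::setNames(tabs, nms), class = "music_barcode_tables")
}
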