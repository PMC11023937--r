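#' Build an exact-match index over a synthetic reference
#'
#' Seed-and-verify mapper for desk-scale synthetic genomes: queries are
#' located by exact `k`-mer seed lookup on both strands, then verified by
#' full-length exact comparison. This replaces external aligners for
#' simulated data; externally aligned real data enters through
#' [import_alignments()].
#'
#' @param ref A [make_reference()] object.
#' @param k Seed length (must not exceed the shortest query).
#' @return A `music_index` list.
#' @export
build_index <- function(ref, k = 20L) {
  structure(list(seqs = ref$seqs, k = as.integer(k),
                 chrom_len = stats::setNames(ref$chromosomes$length,
                                             ref$chromosomes$chrom),
                 species = stats::setNames(ref$chromosomes$species,
                                           ref$chromosomes$chrom)),
            class = "music_index")
}

# candidate full-length exact hits of `queries` (character) on the index;
# returns tibble(query_idx, chrom, start0, strand)
.exact_hits <- function(queries, index) {
  k <- index$k
  seeds <- substr(queries, 1L, k)
  hits <- list()
  for (str in c("+", "-")) {
    q <- if (str == "+") seeds else rev_comp(seeds)
    pd <- Biostrings::PDict(q)
    for (chrom in names(index$seqs)) {
      m <- Biostrings::matchPDict(pd, index$seqs[[chrom]])
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0) next
      qi <- rep(seq_along(queries), cnt)
      st <- unlist(S4Vectors::start(m), use.names = FALSE)
      qlen <- nchar(queries)[qi]
      if (str == "+") {
        frag_start <- st
      } else {
        # seed is the revcomp of the query prefix; the fragment's leftmost
        # genomic base is seed_end - qlen + 1
        frag_start <- st + k - qlen
      }
      valid <- frag_start >= 1L & frag_start + qlen - 1L <=
        index$chrom_len[[chrom]]
      qi <- qi[valid]; frag_start <- frag_start[valid]; qlen <- qlen[valid]
      if (length(qi) == 0) next
      obs <- as.character(Biostrings::extractAt(
        index$seqs[[chrom]], IRanges::IRanges(frag_start, width = qlen)))
      want <- if (str == "+") queries[qi] else rev_comp(queries[qi])
      keep <- obs == want
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- tibble(
        query_idx = qi[keep], chrom = chrom,
        start0 = frag_start[keep] - 1L, strand = str)
    }
  }
  if (length(hits) == 0) {
    tibble(query_idx = integer(0), chrom = character(0),
           start0 = integer(0), strand = character(0))
  } else {
    dplyr::distinct(dplyr::bind_rows(hits))
  }
}

#' Map tagged reads to the reference
#'
#' Classifies each insert as `unique`, `multi` or `unmapped`; only
#' unique-class reads carry coordinates. Coordinates are 0-based leftmost;
#' `pos5` is the 5' end of the fragment (equal to `start` on "+", rightmost
#' base on "-").
#'
#' @param tagged Tibble of tagged reads (needs an `insert` column; all other
#'   columns are carried through).
#' @param index A [build_index()] object.
#' @return Tibble: input columns + `chrom`, `start`, `strand`, `pos5`,
#'   `map_class`, `species`.
#' @export
map_reads <- function(tagged, index) {
  n <- nrow(tagged)
  out <- tagged
  out$chrom <- NA_character_; out$start <- NA_integer_
  out$strand <- NA_character_; out$map_class <- "unmapped"
  if (n > 0) {
    hits <- .exact_hits(tagged$insert, index)
    cnt <- tabulate(hits$query_idx, nbins = n)
    uni <- which(cnt == 1L)
    out$map_class[cnt > 1L] <- "multi"
    out$map_class[uni] <- "unique"
    h1 <- hits[hits$query_idx %in% uni, ]
    out$chrom[h1$query_idx] <- h1$chrom
    out$start[h1$query_idx] <- h1$start0
    out$strand[h1$query_idx] <- h1$strand
  }
  out$pos5 <- if_else(out$strand == "-",
                      out$start + nchar(out$insert) - 1L, out$start)
  out$species <- unname(index$species[out$chrom])
  out
}

#' Map a single insert
#'
#' Scalar convenience around the same exact seed-and-verify lookup as
#' [map_reads()].
#'
#' @param insert A single sequence.
#' @param index A [build_index()] object.
#' @return One-row tibble with `chrom`, `start` (0-based), `strand`,
#'   `map_class`.
#' @export
map_insert <- function(insert, index) {
  r <- map_reads(tibble(insert = insert), index)
  dplyr::select(r, "chrom", "start", "strand", "map_class")
}

#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance (wraps [utils::adist()]).
#'
#' @param a,b Character vectors (recycled).
#' @return Integer vector of distances.
#' @export
edit_distance <- function(a, b) {
  as.integer(diag(utils::adist(a, b)))
}

#' Remove PCR duplicates by the three-criterion scan
#'
#' Input must be sorted by (chromosome, start). A read is flagged as a
#' duplicate iff an already-retained read on the same chromosome and strand
#' (i) lies within 8 bp of its 5' start, (ii) shares all five barcodes
#' (cb1, cb2, cb3, GEM, I7) and (iii) has a UMI (the 17-nt concatenation of
#' GEM UMI and linker UMI) within Levenshtein distance < 2.
#'
#' @param reads Mapped-read tibble (unique-class reads), sorted by
#'   (`chrom`, `start`).
#' @param window Maximum 5'-start separation in bp.
#' @param max_umi_dist Duplicates require UMI distance strictly below this.
#' @return List: `reads` (retained tibble), `n_duplicates`.
#' @export
deduplicate <- function(reads, window = 8L, max_umi_dist = 2L) {
  if (nrow(reads) == 0) return(list(reads = reads, n_duplicates = 0L))
  o <- order(reads$chrom, reads$start)
  if (!identical(o, seq_len(nrow(reads)))) {
    stop("deduplicate() requires input sorted by (chrom, start)")
  }
  umi <- paste0(reads$gem_umi, reads$linker_umi)
  key <- paste(reads$chrom, reads$strand, reads$cb1, reads$cb2, reads$cb3,
               reads$gem, reads$i7, sep = "\r")
  dup <- logical(nrow(reads))
  idx_by_key <- split(seq_len(nrow(reads)), key)
  for (idx in idx_by_key) {
    if (length(idx) == 1L) next
    kept_pos <- integer(0); kept_umi <- character(0)
    for (i in idx) {  # idx is in (chrom, start) order within the group
      p <- reads$pos5[i]
      near <- which(abs(kept_pos - p) <= window)
      is_dup <- FALSE
      if (length(near) > 0) {
        d <- utils::adist(umi[i], kept_umi[near])
        is_dup <- any(d < max_umi_dist)
      }
      if (is_dup) {
        dup[i] <- TRUE
      } else {
        kept_pos <- c(kept_pos, p); kept_umi <- c(kept_umi, umi[i])
      }
    }
  }
  list(reads = reads[!dup, ], n_duplicates = sum(dup))
}

#' Import externally aligned reads from BAM
#'
#' Reads primary alignments carrying the tag set written by the demux stage
#' (CB/CD/CE = cell barcodes 1-3, GB = GEM id, GU = GEM UMI, IB = I7 id,
#' LU = linker UMI, MO = modality) and derives the mapping class from flags
#' and MAPQ (unique iff primary and MAPQ >= `min_mapq`).
#'
#' @param bam Path to a BAM file.
#' @param index A [build_index()] (for species lookup); optional.
#' @param min_mapq MAPQ threshold for the unique class.
#' @return List: `reads` (MappedRead tibble), `n_rejected` (records missing a
#'   required tag).
#' @export
import_alignments <- function(bam, index = NULL, min_mapq = 30L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for BAM import")
  }
  tags <- c("CB", "CD", "CE", "GB", "GU", "IB", "LU", "MO")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "seq"),
    tag = tags,
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  tg <- b$tag
  n <- length(b$qname)
  has_tags <- Reduce(`&`, lapply(tags, function(t) {
    v <- tg[[t]]
    if (is.null(v)) rep(FALSE, n) else !is.na(v)
  }))
  keep <- which(has_tags)
  unmapped <- bitwAnd(b$flag[keep], 4L) != 0L
  reads <- tibble(
    read_id = b$qname[keep],
    cb1 = as.integer(tg$CB[keep]), cb2 = as.integer(tg$CD[keep]),
    cb3 = as.integer(tg$CE[keep]),
    gem = as.integer(tg$GB[keep]), gem_umi = as.character(tg$GU[keep]),
    i7 = as.integer(tg$IB[keep]), linker_umi = as.character(tg$LU[keep]),
    modality = as.character(tg$MO[keep]),
    insert = as.character(b$seq[keep]),
    chrom = as.character(b$rname[keep]),
    start = b$pos[keep] - 1L,
    strand = as.character(b$strand[keep]),
    map_class = dplyr::case_when(
      unmapped ~ "unmapped",
      b$mapq[keep] >= min_mapq ~ "unique",
      TRUE ~ "multi"))
  reads$chrom[reads$map_class != "unique"] <- NA_character_
  reads$start[reads$map_class != "unique"] <- NA_integer_
  reads$pos5 <- if_else(reads$strand == "-",
                        reads$start + nchar(reads$insert) - 1L, reads$start)
  reads$species <- if (!is.null(index)) {
    unname(index$species[reads$chrom])
  } else NA_character_
  list(reads = reads, n_rejected = n - length(keep))
}
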