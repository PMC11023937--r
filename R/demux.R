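#' Match an observed barcode against a whitelist
#'
#' Returns the id (position) of the unique whitelist entry within
#' `max_mismatch` Hamming distance of the observed sequence, or `NA` when no
#' entry or more than one entry qualifies (ambiguous assignments are never
#' made).
#'
#' @param observed Character vector of observed sequences (same length as the
#'   whitelist entries).
#' @param table Character vector whitelist.
#' @param max_mismatch Maximum Hamming distance.
#' @return Integer vector of ids (`NA` = unassigned).
#' @export
match_barcode <- function(observed, table, max_mismatch = 1L) {
  L <- nchar(table[1])
  bad <- nchar(observed) != L
  ids <- match(observed, table)
  todo <- which(is.na(ids) & !bad)
  if (max_mismatch > 0 && length(todo) > 0) {
    obs_mat <- matrix(unlist(strsplit(observed[todo], "")), nrow = L)
    n_cand <- integer(length(todo))
    best <- integer(length(todo))
    for (j in seq_along(table)) {
      tj <- strsplit(table[j], "")[[1]]
      mm <- colSums(obs_mat != tj)
      hit <- mm <= max_mismatch
      n_cand <- n_cand + hit
      best[hit] <- j
    }
    ids[todo[n_cand == 1L]] <- best[n_cand == 1L]
  }
  ids[bad] <- NA_integer_
  ids
}

# mismatches of each string in x (all nchar L) against constant pattern p
.mm_const <- function(x, p) {
  L <- nchar(p)
  if (length(x) == 0) return(integer(0))
  pm <- strsplit(p, "")[[1]]
  xm <- matrix(unlist(strsplit(substr(x, 1L, L), "")), nrow = L)
  colSums(xm != pm)
}

#' Classify the modality of an R2 linker region
#'
#' The region following the cell-barcode prefix starts with the shared
#' `CGAGGAG` bases; RNA is called when `CGCTT` + UMI + `ATAGCATTGC` follows
#' with at most 1 mismatch per fixed segment, DNA when UMI +
#' `ACAACGCACAGTGTCTAGT` follows with at most 2 mismatches. Reads matching
#' both or neither are `unknown`.
#'
#' @param linker_region Character vector: R2 starting at the linker offset.
#' @param layout A [music_layout()].
#' @return Tibble with `modality` ("RNA"/"DNA"/"unknown"), `linker_umi` and
#'   `insert_offset` (1-based offset of the insert within the linker region).
#' @export
classify_modality <- function(linker_region, layout = music_layout()) {
  n <- length(linker_region)
  pre_len <- nchar(layout$shared_prefix)
  pre_ok <- .mm_const(linker_region, layout$shared_prefix) <= 1L
  body <- substr(linker_region, pre_len + 1L, nchar(linker_region))
  u <- layout$linker_umi_len
  s1 <- nchar(layout$rna_sig1)
  rna_ok <- pre_ok &
    .mm_const(body, layout$rna_sig1) <= 1L &
    .mm_const(substr(body, s1 + u + 1L, nchar(body)), layout$rna_sig2) <= 1L
  dna_ok <- pre_ok &
    .mm_const(substr(body, u + 1L, nchar(body)), layout$dna_sig) <= 2L
  modality <- rep("unknown", n)
  modality[rna_ok & !dna_ok] <- "RNA"
  modality[dna_ok & !rna_ok] <- "DNA"
  umi <- rep(NA_character_, n)
  umi[modality == "RNA"] <- substr(body[modality == "RNA"], s1 + 1L, s1 + u)
  umi[modality == "DNA"] <- substr(body[modality == "DNA"], 1L, u)
  offset <- rep(NA_integer_, n)
  offset[modality == "RNA"] <- layout$rna_linker_len + 1L
  offset[modality == "DNA"] <- layout$dna_linker_len + 1L
  tibble(modality = modality, linker_umi = umi, insert_offset = offset)
}

# cutadapt-style 3' quality trimming: subtract the cutoff from each quality,
# take partial sums from the 3' end, cut where that sum is minimal (< 0)
.qual_trim_len <- function(qual, cutoff = 15L) {
  q <- utf8ToInt(qual) - 33L - cutoff
  s <- rev(cumsum(rev(q)))
  cut <- which(s == min(s, 0))
  if (length(cut) && min(s) < 0) max(cut) - 1L else length(q)
}

#' Trim an insert per modality rules
#'
#' DNA: a terminal homopolymer run of A or of G longer than 20 bp is removed.
#' RNA: at the first occurrence of the RNA linker ssDNA signature
#' (`CGAGGAGCGCTT`) the signature and everything 3' of it is removed. Both:
#' 3' quality trimming at Q15 (running-sum rule), then drop below `min_length`.
#'
#' @param insert,qual Character vectors of equal-length sequences/qualities.
#' @param modality "RNA" or "DNA" per read.
#' @param layout A [music_layout()].
#' @param min_length Minimum surviving length (dropped below it).
#' @param qual_cutoff Phred cutoff for 3' quality trimming.
#' @return Tibble with `insert`, `qual`, `kept` (FALSE = dropped).
#' @export
trim_insert <- function(insert, qual = strrep("?", nchar(insert)), modality,
                        layout = music_layout(), min_length = 20L,
                        qual_cutoff = 15L) {
  n <- length(insert)
  out <- insert
  # DNA 3' homopolymer artifact
  is_dna <- modality == "DNA"
  if (any(is_dna)) {
    runs <- stringr::str_match(out[is_dna], "(A{21,}|G{21,})$")[, 1]
    hit <- !is.na(runs)
    out[is_dna][hit] <- substr(out[is_dna][hit], 1L,
                               nchar(out[is_dna][hit]) - nchar(runs[hit]))
  }
  # RNA linker read-through
  is_rna <- modality == "RNA"
  if (any(is_rna)) {
    sig <- paste0(layout$shared_prefix, layout$rna_sig1)
    pos <- stringr::str_locate(out[is_rna], stringr::fixed(sig))[, 1]
    hit <- !is.na(pos)
    out[is_rna][hit] <- substr(out[is_rna][hit], 1L, pos[hit] - 1L)
  }
  qual <- substr(qual, 1L, nchar(out))
  qlen <- vapply(qual, .qual_trim_len, integer(1), cutoff = qual_cutoff,
                 USE.NAMES = FALSE)
  out <- substr(out, 1L, qlen)
  qual <- substr(qual, 1L, qlen)
  kept <- nchar(out) >= min_length
  tibble(insert = out, qual = qual, kept = kept)
}

#' Parse read triples into tagged reads
#'
#' Applies whitelist matching (1 mismatch allowed per cell barcode, exact GEM
#' match with 1-mismatch whitelist rescue, exact I7), linker classification
#' and insert trimming. Every input read is either tagged or rejected with a
#' machine-readable reason, and the two counts partition the input exactly.
#'
#' @param records Tibble with `read_id`, `r1`, `i1`, `r2`, `q2` (as produced
#'   by [emit_reads()] or [demux_fastq()]).
#' @param tables A [music_barcode_tables()].
#' @param layout A [music_layout()].
#' @param min_insert Minimum insert length after trimming.
#' @return List: `tagged` (tibble: read_id, cb1..cb3, gem, gem_umi, i7,
#'   linker_umi, modality, insert, qual), `rejected` (read_id, reason),
#'   `report` (named counts).
#' @export
parse_read_pairs <- function(records, tables, layout = music_layout(),
                             min_insert = 20L) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  lay <- layout
  struct_ok <- nchar(records$r1) >= lay$gem_len + lay$gem_umi_len &
    nchar(records$i1) == lay$i7_len &
    nchar(records$r2) > lay$linker_offset + lay$rna_linker_len
  reason[!struct_ok] <- "structure"

  cb_len <- lay$cb_len
  o3 <- 1L
  o2 <- cb_len + nchar(lay$spacer1) + 1L
  o1 <- o2 + cb_len + nchar(lay$spacer2)
  cb3 <- match_barcode(substr(records$r2, o3, o3 + cb_len - 1L), tables$cb3)
  cb2 <- match_barcode(substr(records$r2, o2, o2 + cb_len - 1L), tables$cb2)
  cb1 <- match_barcode(substr(records$r2, o1, o1 + cb_len - 1L), tables$cb1)
  gem <- match_barcode(substr(records$r1, 1L, lay$gem_len), tables$gem,
                       max_mismatch = 1L)
  gem_umi <- substr(records$r1, lay$gem_len + 1L,
                    lay$gem_len + lay$gem_umi_len)
  i7 <- match_barcode(records$i1, tables$i7, max_mismatch = 0L)

  ok <- struct_ok
  for (nm in c("cb1", "cb2", "cb3", "gem", "i7")) {
    v <- get(nm)
    miss <- ok & is.na(v)
    reason[miss] <- nm
    ok <- ok & !miss
  }

  linker_region <- substr(records$r2, lay$linker_offset + 1L,
                          nchar(records$r2))
  cls <- classify_modality(linker_region, lay)
  miss <- ok & cls$modality == "unknown"
  reason[miss] <- "linker"
  ok <- ok & !miss

  insert <- substr(linker_region, cls$insert_offset, nchar(linker_region))
  qual <- substr(records$q2, lay$linker_offset + cls$insert_offset,
                 nchar(records$q2))
  insert[!ok] <- ""
  qual[!ok] <- ""
  tr <- trim_insert(insert, qual, cls$modality, lay, min_length = min_insert)
  miss <- ok & !tr$kept
  reason[miss] <- "insert_short"
  ok <- ok & !miss

  tagged <- tibble(
    read_id = records$read_id, cb1 = cb1, cb2 = cb2, cb3 = cb3,
    gem = gem, gem_umi = gem_umi, i7 = i7, linker_umi = cls$linker_umi,
    modality = cls$modality, insert = tr$insert, qual = tr$qual)[ok, ]
  rejected <- tibble(read_id = records$read_id, reason = reason)[!ok, ]
  report <- list(
    input = n, tagged = nrow(tagged), rejected = nrow(rejected),
    by_reason = as.list(table(rejected$reason)),
    barcode_complete = sum(!is.na(cb1) & !is.na(cb2) & !is.na(cb3) &
                             !is.na(gem) & !is.na(i7) & struct_ok))
  list(tagged = tagged, rejected = rejected, report = report)
}

#' Demultiplex a FASTQ triplet
#'
#' Reads the three FASTQ files (read order must agree), then calls
#' [parse_read_pairs()].
#'
#' @param r1,i1,r2 FASTQ paths.
#' @param tables A [music_barcode_tables()].
#' @param layout A [music_layout()].
#' @param ... Passed to [parse_read_pairs()].
#' @return As [parse_read_pairs()].
#' @export
demux_fastq <- function(r1, i1, r2, tables, layout = music_layout(), ...) {
  f1 <- read_fastq(r1); fi <- read_fastq(i1); f2 <- read_fastq(r2)
  if (!identical(f1$read_id, fi$read_id) ||
      !identical(f1$read_id, f2$read_id)) {
    stop("FASTQ triplet is out of sync: read names differ")
  }
  records <- tibble(read_id = f1$read_id, r1 = f1$seq, i1 = fi$seq,
                    r2 = f2$seq, q2 = f2$qual)
  parse_read_pairs(records, tables, layout, ...)
}
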