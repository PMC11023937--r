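test_that("exact mapper locates substrings on both strands and flags repeats", {
  ref <- fx_ref()
  idx <- fx_index()
  chr1 <- as.character(ref$seqs[["chr1"]])
  q <- substr(chr1, 501, 540)
  hit <- map_insert(q, idx)
  expect_equal(hit$map_class, "unique")
  expect_equal(hit$chrom, "chr1")
  expect_equal(hit$start, 500L)  # 0-based
  expect_equal(hit$strand, "+")

  rc <- map_insert(rev_comp(q), idx)
  expect_equal(rc$map_class, "unique")
  expect_equal(rc$start, 500L)
  expect_equal(rc$strand, "-")

  # plant the same 40-mer at two loci of a custom genome
  rep_seq <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  genome <- paste0(substr(chr1, 1, 200), rep_seq, substr(chr1, 241, 800),
                   rep_seq, substr(chr1, 841, 1200))
  ref2 <- fx_ref()
  ref2$seqs <- Biostrings::DNAStringSet(c(chrR = genome))
  ref2$chromosomes <- tibble::tibble(species = "human", chrom = "chrR",
                                     length = nchar(genome),
                                     arm_boundary = 600L, is_x = FALSE)
  multi <- map_insert(rep_seq, build_index(ref2))
  expect_equal(multi$map_class, "multi")

  unmapped <- map_insert(strrep("ACGT", 10), idx)
  expect_equal(unmapped$map_class, "unmapped")
})

test_that("zero-noise mapping reproduces the truth coordinates exactly", {
  run <- fx_run()
  mapped <- run$pp$mapped
  expect_true(all(mapped$map_class == "unique"))
  j <- dplyr::inner_join(mapped, run$em$truth, by = "read_id",
                         suffix = c("", ".t"))
  expect_identical(j$chrom, j$chrom.t)
  expect_identical(j$start, j$start.t)
  expect_identical(j$strand, j$strand.t)
})

test_that("edit distance agrees with a dynamic-programming oracle and is a metric", {
  expect_equal(edit_distance("ACGTACGTACGT", "ACGTACGTACGT"), 0L)
  expect_equal(edit_distance("AAAAA", "AAAAT"), 1L)
  expect_equal(edit_distance("AAAAA", "AATTA"), 2L)
  # independent DP oracle
  lev <- function(a, b) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    d <- matrix(0L, length(a) + 1L, length(b) + 1L)
    d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
    for (i in seq_along(a)) for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
    }
    d[length(a) + 1L, length(b) + 1L]
  }
  set.seed(4)
  seqs <- replicate(12, paste(sample(c("A", "C", "G", "T"),
                                     sample(4:9, 1), TRUE), collapse = ""))
  for (i in 1:11) {
    a <- seqs[i]; b <- seqs[i + 1]; c3 <- seqs[sample(12, 1)]
    expect_equal(edit_distance(a, b), lev(a, b))
    expect_equal(edit_distance(a, b), edit_distance(b, a))        # symmetry
    expect_lte(edit_distance(a, b),
               edit_distance(a, c3) + edit_distance(c3, b))       # triangle
  }
})

test_that("deduplication applies the three-criterion rule at its boundaries", {
  base <- tibble::tibble(
    read_id = c("r1", "r2"), cb1 = 1L, cb2 = 2L, cb3 = 3L, gem = 4L,
    i7 = 1L, gem_umi = c("AAAACCCCGGGG", "AAAACCCCGGGT"),
    linker_umi = "ACGTA", modality = "DNA", chrom = "chr1",
    start = c(100L, 105L), strand = "+", pos5 = c(100L, 105L))
  # within 8 bp, same barcodes, UMI 1 edit apart (< 2): duplicate
  out <- deduplicate(base)
  expect_equal(nrow(out$reads), 1L)
  expect_equal(out$n_duplicates, 1L)
  # 9 bp apart: both retained (9 > 8)
  far <- dplyr::mutate(base, start = c(100L, 109L), pos5 = start)
  expect_equal(nrow(deduplicate(far)$reads), 2L)
  # same position, different GEM: both retained
  dg <- dplyr::mutate(base, start = 100L, pos5 = 100L, gem = c(4L, 5L))
  expect_equal(nrow(deduplicate(dg)$reads), 2L)
  # UMI 2 edits apart: both retained
  du <- dplyr::mutate(base, gem_umi = c("AAAACCCCGGGG", "AAAACCCCGGTT"))
  expect_equal(nrow(deduplicate(du)$reads), 2L)
  # opposite strands are distinct ligation events
  ds <- dplyr::mutate(base, strand = c("+", "-"), pos5 = c(100L, 144L))
  expect_equal(nrow(deduplicate(ds)$reads), 2L)
  # unsorted input errors out
  expect_error(deduplicate(base[2:1, ]), "sorted")
})

test_that("deduplication is idempotent and exact on injected duplicates", {
  gt <- simulate_ground_truth(
    fx_ref(), sim_config(n_cells = 20L, complexes_per_cell = 10L,
                         duplicate_rate = 0.6),
    seed = 43, tables = fx_tables())
  em <- emit_reads(gt, seed = 43)
  pp <- run_pipeline(em$records, fx_tables(), fx_index())
  expect_equal(nrow(pp$dedup), nrow(gt$molecules))
  again <- deduplicate(dplyr::arrange(pp$dedup, chrom, start))
  expect_equal(nrow(again$reads), nrow(pp$dedup))
  expect_equal(again$n_duplicates, 0L)
})

test_that("BAM import reproduces the native mapping path", {
  skip_if_not_installed("Rsamtools")
  run <- fx_run()
  reads <- run$pp$dedup[1:50, ]
  lens <- setNames(fx_ref()$chromosomes$length, fx_ref()$chromosomes$chrom)
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(lens), "\tLN:", lens))
  reads <- dplyr::arrange(reads, chrom, start)
  body <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tCB:i:%d\tCD:i:%d\tCE:i:%d\tGB:i:%d\tGU:Z:%s\tIB:i:%d\tLU:Z:%s\tMO:Z:%s",
    reads$read_id, ifelse(reads$strand == "-", 16L, 0L), reads$chrom,
    reads$start + 1L, nchar(reads$insert),
    ifelse(reads$strand == "-", rev_comp(reads$insert), reads$insert),
    reads$cb1, reads$cb2, reads$cb3, reads$gem, reads$gem_umi, reads$i7,
    reads$linker_umi, reads$modality)
  # one secondary record and one record with a missing GEM tag
  fwd <- which(reads$strand == "+")[1]
  sec <- sub("\t0\t", "\t256\t", body[fwd])
  sec <- sub("^\\S+", "sec1", sec)
  notag <- sub("\tGB:i:\\d+", "", body[2])
  notag <- sub("^\\S+", "notag1", notag)
  writeLines(c(hdr, body, sec, notag), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  imp <- import_alignments(bam, fx_index())
  expect_equal(imp$n_rejected, 1L)  # the tag-less record
  expect_false("sec1" %in% imp$reads$read_id)
  got <- dplyr::arrange(imp$reads, read_id)
  want <- dplyr::arrange(reads, read_id)
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$start, want$start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$cb1, want$cb1)
  expect_equal(got$modality, want$modality)
  expect_true(all(got$map_class == "unique"))
})
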