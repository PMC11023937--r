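find_introned_gene <- function(ref) {
  introns <- reference_introns(ref)
  introns <- introns[introns$biotype == "protein_coding" &
                       introns$end - introns$start >= 40, ]
  introns[1, ]
}

test_that("RNA annotation is strand-aware with the 15-bp intron rule", {
  ref <- fx_ref()
  intr <- find_introned_gene(ref)
  mk_read <- function(start0, len, strand) {
    tibble::tibble(chrom = intr$chrom, start = start0, length = len,
                   strand = strand)
  }
  # 30 bp fully inside the intron, same strand -> pre-mRNA
  inside <- annotate_rna_reads(mk_read(intr$start + 4L, 30L, intr$strand), ref)
  expect_equal(inside$rna_class, "pre-mRNA")
  expect_equal(inside$gene_id, intr$gene_id)
  # 14 bp of intron overlap -> not pre-mRNA (boundary)
  fourteen <- annotate_rna_reads(
    mk_read(intr$start - 1L - 16L, 30L, intr$strand), ref)
  expect_false(fourteen$rna_class == "pre-mRNA")
  # antisense read over the same intron -> not pre-mRNA
  anti <- annotate_rna_reads(
    mk_read(intr$start + 4L, 30L, setdiff(c("+", "-"), intr$strand)), ref)
  expect_false(anti$rna_class == "pre-mRNA")
  # intergenic read
  off <- annotate_rna_reads(
    tibble::tibble(chrom = "chr1", start = 10L, length = 20L, strand = "+"),
    ref)
  expect_equal(off$rna_class, "intergenic")
})

test_that("gene-level quantification reports reads per kilobase", {
  ref <- fx_ref()
  g <- ref$genes[1, ]
  reads <- tibble::tibble(chrom = g$chrom, start = g$start + c(0L, 10L, 20L),
                          length = 30L, strand = g$strand)
  q <- quantify_rna(annotate_rna_reads(reads, ref), ref)
  expect_equal(q$n_reads[q$gene_id == g$gene_id], 3L)
  expect_equal(q$rpk[q$gene_id == g$gene_id],
               3 / ((g$end - g$start + 1) / 1000))
})

test_that("RAL tracks weight DNA ends by 1/(cluster size) under the size cap", {
  lens <- c(chr1 = 2e8)
  reads <- make_cluster_reads(2, 1, pos = c(2.5e6, 7.5e6, 1.2e6),
                              gene_id = c("XIST_LIKE", NA, NA))
  sel <- function(r) !is.na(r$gene_id) & r$gene_id == "XIST_LIKE"
  tr <- ral_track(reads, sel, lens)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$ral, c(1 / 3, 1 / 3))
  expect_equal(sum(tr$ral), 2 / 3)  # conservation: M*N/(M+N) with M=1, N=2
  # a cluster of 1,200 members is excluded by the cap
  big <- make_cluster_reads(1199, 1,
                            pos = c(seq(1e4, by = 50, length.out = 1199), 5e6),
                            gene_id = c("XIST_LIKE",
                                        rep(NA_character_, 1199)))
  expect_equal(nrow(ral_track(big, sel, lens)), 0L)
  # selector matching nothing -> empty track
  none <- ral_track(reads, function(r) rep(FALSE, nrow(r)), lens)
  expect_equal(nrow(none), 0L)
})

test_that("RNA-DNA maps are oriented RNA-bin x DNA-bin with conserved rows", {
  # helper emits RNA members first: RNA end at 1.7 Mb, DNA end at 4.2 Mb
  reads <- make_cluster_reads(1, 1, pos = c(1.7e6, 4.2e6),
                              gene_id = c("G1", NA))
  m <- rna_dna_matrix(reads, "chr1", 1e7)
  expect_equal(m$tbl$rna_bin, 2L)   # RNA end at 1.7 Mb
  expect_equal(m$tbl$dna_bin, 5L)   # DNA end at 4.2 Mb
  expect_equal(m$tbl$weight, 0.5)
  expect_false(isSymmetric(m$dense))
  expect_equal(sum(m$dense[2, ]), 0.5)  # row sum = per-RNA-bin weight
})

test_that("XAL counts distinct XIST-attached megabase bins per cell", {
  mk <- function(cell, key, dna_mb, with_xist = TRUE) {
    n_dna <- length(dna_mb)
    tibble::tibble(
      cell_id = cell, cluster_key = key,
      modality = c(rep("RNA", with_xist), rep("DNA", n_dna)),
      chrom = "chrX", pos5 = as.integer(c(if (with_xist) 1e5,
                                          dna_mb * 1e6 + 5e5)),
      strand = "+",
      gene_id = c(if (with_xist) "XIST_LIKE", rep(NA_character_, n_dna)))
  }
  reads <- dplyr::bind_rows(
    mk("cellA", "k1", c(2, 2)), mk("cellA", "k2", 6),
    mk("cellB", "k3", c(1, 3), with_xist = FALSE))
  x <- xal(reads, "chrX", 1.5e8)
  expect_equal(x$xal[x$cell_id == "cellA"], 2L)  # bins {3, 3, 7} -> 2
  expect_equal(x$xal[x$cell_id == "cellB"], 0L)
  # adding DNA-only clusters never changes XAL
  extra <- mk("cellA", "k9", c(10, 11, 12), with_xist = FALSE)
  x2 <- xal(dplyr::bind_rows(reads, extra), "chrX", 1.5e8)
  expect_equal(x2$xal[x2$cell_id == "cellA"],
               x$xal[x$cell_id == "cellA"])
})

test_that("XAL stratification partitions cells into zero + three equal groups", {
  rec <- tibble::tibble(cell_id = paste0("c", 1:8),
                        xal = c(0L, 0L, 1L, 2L, 3L, 4L, 5L, 6L),
                        n_xist_rna = 0L, n_chrx_dna = 0L)
  s <- stratify_by_xal(rec)
  expect_equal(sum(s$group == "zero"), 2L)
  expect_equal(as.integer(table(s$group)[c("low", "medium", "high")]),
               c(2L, 2L, 2L))
  expect_true(all(s$xal[s$group == "high"] >= s$xal[s$group == "low"]))
  all_zero <- stratify_by_xal(dplyr::mutate(rec, xal = 0L))
  expect_true(all(all_zero$group == "zero"))
  three <- stratify_by_xal(rec[c(1, 3, 4, 5), ])
  expect_equal(as.integer(table(three$group)),
               c(1L, 1L, 1L, 1L))
})

test_that("XIST+/- split recovers a planted long-range difference", {
  set.seed(55)
  n <- 400L
  mk_pairs <- function(prefix, dist_fun, xist) {
    d <- dist_fun(n)
    a <- floor(runif(n, 0, 1.4e8 - max(d)))
    purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(
        cell_id = "cellF", cluster_key = sprintf("%s%05d", prefix, i),
        modality = c(if (xist) "RNA", "DNA", "DNA"),
        chrom = "chrX",
        pos5 = as.integer(c(if (xist) 1e5, a[i], a[i] + d[i])),
        strand = "+",
        gene_id = c(if (xist) "XIST_LIKE", NA, NA))
    })
  }
  # XIST+ complexes carry a heavier long-range tail
  pos_reads <- mk_pairs("X", function(n) round(10^runif(n, 6.5, 8)), TRUE)
  neg_reads <- mk_pairs("N", function(n) round(10^runif(n, 4, 6.5)), FALSE)
  split <- xist_split_pc(dplyr::bind_rows(pos_reads, neg_reads), "chrX",
                         mode = "pool_all")
  mass_below <- function(cv, s) sum(cv$freq[cv$s_mid < s]) / sum(cv$freq)
  expect_gt(mass_below(split$neg, 3e6), mass_below(split$pos, 3e6))
  expect_gt(1 - mass_below(split$pos, 3e6), 1 - mass_below(split$neg, 3e6))

  # no XIST reads at all: positive set is empty
  none <- xist_split_pc(neg_reads, "chrX")
  expect_null(none$pos)

  # any-RNA control on a symmetric simulation: indistinguishable distances
  rna_pairs <- mk_pairs("R", function(n) round(10^runif(n, 4, 7)), TRUE)
  dna_pairs <- mk_pairs("D", function(n) round(10^runif(n, 4, 7)), FALSE)
  both <- dplyr::bind_rows(rna_pairs, dna_pairs)
  cc_pos <- decompose_contacts(rna_pairs, type = "dna_dna")
  cc_neg <- decompose_contacts(dna_pairs, type = "dna_dna")
  ks <- suppressWarnings(stats::ks.test(abs(cc_pos$pos_a - cc_pos$pos_b),
                                        abs(cc_neg$pos_a - cc_neg$pos_b)))
  expect_gt(ks$p.value, 0.05)
  # the curves themselves exist for both sides of the control split
  ctl <- xist_split_pc(both, "chrX", split = "any_rna", mode = "pool_all")
  expect_false(is.null(ctl$pos))
  expect_false(is.null(ctl$neg))
})
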