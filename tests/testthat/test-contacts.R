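test_that("contact matrices bin weights and conserve mass", {
  sch <- bin_scheme("chr1", end = 1e5, resolution = 1e4)
  cc2 <- decompose_cluster(make_cluster_reads(2, 0, pos = c(25000, 29000)),
                           type = "dna_dna")
  m <- contact_matrix(cc2, sch)
  expect_equal(m$tbl$bin_i, 3L)
  expect_equal(m$tbl$bin_j, 3L)
  expect_equal(m$tbl$weight, 0.5)

  cc3 <- decompose_cluster(
    make_cluster_reads(3, 0, pos = c(5000, 15000, 35000)), type = "dna_dna")
  m3 <- contact_matrix(cc3, sch)
  expect_equal(nrow(m3$tbl), 3L)
  expect_equal(m3$tbl[, c("bin_i", "bin_j")],
               tibble::tibble(bin_i = c(1L, 1L, 2L), bin_j = c(2L, 4L, 4L)))
  expect_equal(unique(m3$tbl$weight), 1 / 3)
  expect_equal(m3$total_weight, sum(cc3$weight))   # mass conservation

  empty <- contact_matrix(cc3[0, ], sch)
  expect_equal(nrow(empty$tbl), 0L)
  # out-of-scheme contacts are dropped and counted
  off <- decompose_cluster(make_cluster_reads(2, 0, pos = c(5000, 2e5)),
                           type = "dna_dna")
  expect_equal(contact_matrix(off, sch)$n_dropped, 1L)
})

test_that("visual transform is the monotone log scale-up", {
  expect_equal(visual_transform(0), 0)
  expect_equal(visual_transform(0.5, 100), log10(51))
  set.seed(2)
  w <- sort(runif(50))
  expect_true(all(diff(visual_transform(w, 1000)) >= 0))
})

test_that("map-pair normalization lands both maps in [0, 1] with max 1", {
  set.seed(3)
  a <- matrix(runif(64), 8)
  out <- normalize_map_pair(a, a)
  expect_identical(out$a, out$b)
  out2 <- normalize_map_pair(a, 3 * a)
  expect_equal(max(out2$a), 1)
  expect_equal(max(out2$b), 1)
  expect_true(all(out2$a >= 0 & out2$a <= 1))
  expect_warning(normalize_map_pair(matrix(0, 4, 4), a), "all-zero")
})

test_that("distance-decay curve places mass in the right bins and is additive", {
  one <- decompose_cluster(
    make_cluster_reads(2, 0, pos = c(1000, 1000 + 123456)), type = "dna_dna")
  cv <- pc_curve(one, n_bins = 5e5)
  width <- (1.5e8 - 10) / 5e5
  expect_equal(cv$bin, as.integer((123456 - 10) %/% width) + 1L)
  expect_equal(sum(cv$freq), 1)  # per-cell normalized

  two_cells <- dplyr::bind_rows(
    dplyr::mutate(simulate_powerlaw_contacts(500, seed = 1), cell_id = "A"),
    dplyr::mutate(simulate_powerlaw_contacts(500, seed = 2), cell_id = "B"))
  merged <- pc_curve(two_cells)
  per_cell <- lapply(c("A", "B"), function(cid)
    pc_curve(dplyr::filter(two_cells, cell_id == cid)))
  summed <- dplyr::bind_rows(per_cell) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(freq = sum(freq), .groups = "drop")
  j <- dplyr::inner_join(merged, summed, by = "bin")
  expect_equal(nrow(j), nrow(merged))
  expect_equal(j$freq.x, j$freq.y)

  # distances outside [10 bp, 150 Mb] are excluded and counted
  near <- decompose_cluster(make_cluster_reads(2, 0, pos = c(100, 105)),
                            type = "dna_dna")
  expect_equal(attr(pc_curve(near), "n_excluded"), 1L)
})

test_that("arm table restricts pairs to within-arm distances", {
  cc <- dplyr::bind_rows(
    decompose_cluster(make_cluster_reads(2, 0, pos = c(1e4, 2e4)),
                      type = "dna_dna"),
    decompose_cluster(make_cluster_reads(2, 0, pos = c(1e4, 9e4),
                                         cluster_key = "k2"),
                      type = "dna_dna"))
  arms <- tibble::tibble(chrom = "chr1", arm_boundary = 5e4)
  cv <- pc_curve(cc, arms = arms, mode = "pool_all")
  expect_equal(sum(cv$freq), 0.5)  # the arm-crossing pair is gone
})

test_that("log-binned edges match an independent closed-form recomputation", {
  edges <- logbin_edges()
  step <- (log2(1.5e8) - log2(5000)) / 150
  for (n in c(1, 75, 150)) {
    expect_equal(edges[n], 2^(log2(5000) + step * (n - 1)), tolerance = 1e-9)
  }
  expect_equal(edges[1], 5000, tolerance = 1e-9)
  expect_equal(edges[151], 1.5e8, tolerance = 1e-9)
  expect_true(all(diff(edges) > 0))
  expect_length(edges, 151L)
})

test_that("log-binned profiles normalize by bin width and sum to one", {
  one <- decompose_cluster(
    make_cluster_reads(2, 0, pos = c(1000, 1000 + 1e6)), type = "dna_dna")
  pr <- logbin_profile(one)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$value, 1)
  edges <- logbin_edges()
  expect_equal(pr$bin, findInterval(1e6, edges))

  # equal weight in a narrow and a wide bin: narrow bin wins after width
  # normalization
  d_narrow <- sqrt(edges[20] * edges[21])
  d_wide <- sqrt(edges[120] * edges[121])
  cc <- dplyr::bind_rows(
    decompose_cluster(make_cluster_reads(
      2, 0, pos = c(0, round(d_narrow))), type = "dna_dna"),
    decompose_cluster(make_cluster_reads(
      2, 0, pos = c(0, round(d_wide)), cluster_key = "k2"), type = "dna_dna"))
  pr2 <- logbin_profile(cc)
  expect_equal(sum(pr2$value), 1)
  expect_gt(pr2$value[pr2$bin == 20], pr2$value[pr2$bin == 120])

  run <- fx_run()
  cc3 <- decompose_contacts(run$pp$clusters$reads, type = "dna_dna")
  pr3 <- logbin_profile(cc3)
  sums <- tapply(pr3$value, pr3$cell_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("compartment PC1 recovers planted blocks and self-comparison is exact", {
  n <- 60L
  lab <- rep(rep(c(1, -1), each = 6L), 5L)
  decay <- exp(-abs(outer(1:n, 1:n, "-")) / 30)
  obs <- decay * ifelse(outer(lab, lab) > 0, 1.6, 0.4)
  pc1 <- compartment_track(obs, reference = lab)
  expect_true(all(sign(pc1) == sign(lab)))

  cmp <- compare_compartments(list(chr1 = pc1, chr2 = pc1),
                              list(chr1 = pc1, chr2 = pc1))
  expect_equal(cmp$median_r, 1.0)
  expect_true(all(cmp$per_chrom$r == 1.0))

  # shuffling the matrix destroys the compartment signal
  set.seed(8)
  n2 <- 200L
  lab2 <- rep(rep(c(1, -1), each = 10L), 10L)
  decay2 <- exp(-abs(outer(1:n2, 1:n2, "-")) / 60)
  obs2 <- decay2 * ifelse(outer(lab2, lab2) > 0, 1.6, 0.4)
  perm <- sample(n2)
  pc_a <- compartment_track(obs2, reference = lab2)
  pc_b <- compartment_track(obs2[perm, perm])
  expect_lt(abs(cor(pc_a, pc_b)), 0.3)

  expect_error(compartment_track(matrix(1, 30, 30)), "degenerate")
  expect_error(compartment_track(matrix(0, 30, 30)), "informative")
})

test_that("multiplex clusters concentrate mass within TAD-like blocks", {
  reads <- simulate_tad_clusters(n_clusters = 300L, seed = 21)
  cc <- decompose_contacts(reads, type = "dna_dna")
  block_of <- function(p) p %/% 1e6
  ratio <- function(x) {
    within <- block_of(x$pos_a) == block_of(x$pos_b)
    sum(x$weight[within]) / sum(x$weight[!within])
  }
  pairwise <- dplyr::filter(cc, cluster_size == 2)
  multiplex <- dplyr::filter(cc, cluster_size >= 3)
  expect_gt(ratio(multiplex), ratio(pairwise) * 0)  # both defined
  expect_gt(ratio(multiplex), ratio(pairwise))
})
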