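test_that("cell QC keeps RNA >= 100 and DNA >= 5000, boundaries inclusive", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                          n_rna = c(100L, 99L, 500L, 100L),
                          n_dna = c(5000L, 1000000L, 4999L, 7000L))
  out <- filter_cells(cells)
  expect_setequal(out$kept$cell_id, c("a", "d"))
  set.seed(6)
  rnd <- tibble::tibble(cell_id = paste0("c", 1:200),
                        n_rna = rpois(200, 120),
                        n_dna = rpois(200, 5000))
  brute <- rnd[rnd$n_rna >= 100 & rnd$n_dna >= 5000, ]
  expect_identical(filter_cells(rnd)$kept, brute)
})

test_that("log-normalization matches hand computation", {
  counts <- matrix(c(0, 5, 45, 10, 10, 80), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  nm <- lognormalize(counts, scale = 1e4)
  expect_equal(nm["g1", "c1"], 0)
  expect_equal(nm["g2", "c1"], log1p(1e4 * 5 / 50))
  expect_equal(nm["g3", "c2"], log1p(1e4 * 80 / 100))
  expect_true(all(diff(nm[order(counts[, 1]), 1]) >= 0))  # monotone per cell
})

test_that("marker scoring assigns planted cell types and breaks ties first", {
  set.seed(7)
  types <- c("Ast", "ExN", "Oli")
  markers <- tibble::tibble(cell_type = rep(types, each = 3),
                            gene_id = paste0("g", 1:9))
  n_per <- 30L
  cells <- paste0("c", seq_len(3 * n_per))
  truth <- rep(types, each = n_per)
  counts <- matrix(rpois(12 * length(cells), 2), nrow = 12,
                   dimnames = list(paste0("g", 1:12), cells))
  for (i in seq_along(types)) {  # 4-fold marker over-expression
    rows <- markers$gene_id[markers$cell_type == types[i]]
    cols <- cells[truth == types[i]]
    counts[rows, cols] <- rpois(length(rows) * length(cols), 8)
  }
  labels <- tibble::tibble(cell_id = cells, cluster = truth)
  got <- assign_cell_types(labels, markers, counts)
  expect_equal(got$cell_type[match(types, got$cluster)], types)

  # exact tie -> lexicographically first, with a warning
  tie_counts <- matrix(5, nrow = 2, ncol = 2,
                       dimnames = list(c("m1", "m2"), c("x", "y")))
  tie_markers <- tibble::tibble(cell_type = c("B", "A"),
                                gene_id = c("m1", "m2"))
  expect_warning(
    tie <- assign_cell_types(tibble::tibble(cell_id = c("x", "y"),
                                            cluster = "k"),
                             tie_markers, tie_counts),
    "tie")
  expect_equal(tie$cell_type, "A")

  # a type with no usable markers is ineligible
  empty_markers <- tibble::tibble(cell_type = c("A", "B"),
                                  gene_id = c("m1", "absent_gene"))
  got2 <- assign_cell_types(tibble::tibble(cell_id = c("x", "y"),
                                           cluster = "k"),
                            empty_markers, tie_counts)
  expect_equal(got2$cell_type, "A")
})

test_that("LCS-erosion score thresholds at 3e5 with top-ten median", {
  short <- decompose_cluster(
    make_cluster_reads(2, 0, pos = c(0, 5e4)), type = "dna_dna")
  pr <- logbin_profile(short)
  sc <- lcs_erosion(pr)
  expect_lt(sc$lcs_score, 1e5)
  expect_equal(sc$lcs_class, "preserved")
  expect_true(sc$low_confidence)  # fewer than 10 non-empty bins

  long <- decompose_cluster(
    make_cluster_reads(2, 0, pos = c(0, 5e7)), type = "dna_dna")
  sc2 <- lcs_erosion(logbin_profile(long))
  expect_gt(sc2$lcs_score, 1e7)
  expect_equal(sc2$lcs_class, "eroded")

  # median of the top-10 midpoints, ties resolved toward smaller distance
  edges <- logbin_edges()
  pr10 <- tibble::tibble(cell_id = "c", bin = 1:12,
                         s_lo = edges[1:12], s_hi = edges[2:13],
                         value = c(rep(0.09, 10), 0.05, 0.05))
  sc3 <- lcs_erosion(pr10)
  mids <- sqrt(edges[1:10] * edges[2:11])
  expect_equal(sc3$lcs_score, median(mids))
})

test_that("two-population mixture is classified by the 3e5 threshold", {
  sim <- simulate_lcs_population(n_cells = 60L, contacts_per_cell = 120L,
                                 seed = 77)
  sc <- lcs_erosion(logbin_profile(sim$contacts))
  j <- dplyr::inner_join(sc, sim$truth, by = "cell_id")
  acc <- mean((j$lcs_class == "eroded") == (j$true_class == "eroded"))
  expect_gte(acc, 0.95)
})

test_that("transcriptomic age is zero for flat expression and monotone per gene", {
  counts <- matrix(5, nrow = 2, ncol = 4,
                   dimnames = list(c("a1", "a2"), paste0("c", 1:4)))
  smpl <- setNames(rep(c("S1", "S2"), 2), colnames(counts))
  ages <- c(S1 = 60, S2 = 80)
  out <- transcriptomic_age(counts, c("a1", "a2"), smpl, ages)
  expect_true(all(out$ages$transcriptomic_age == 0))
  expect_equal(out$n_skipped, 2L)  # zero-variance genes skipped

  # one positively signed gene: increasing expression -> increasing age
  # (identity normalization isolates the direction/weight arithmetic)
  counts2 <- matrix(c(1, 2, 6, 9), nrow = 1,
                    dimnames = list("a1", paste0("c", 1:4)))
  smpl2 <- setNames(c("S1", "S1", "S2", "S2"), colnames(counts2))
  out2 <- transcriptomic_age(counts2, "a1", smpl2, ages,
                             normalized = counts2)
  expect_equal(out2$weights$direction, 1)
  expect_true(all(diff(out2$ages$transcriptomic_age) > 0))
  expect_error(transcriptomic_age(counts2, "a1", smpl2, c(S1 = 70, S2 = 70)),
               "distinct")
})

test_that("transcriptomic age is invariant to per-gene affine rescaling", {
  sim <- simulate_ageing_expression(n_cells = 80L, n_ageing_genes = 10L,
                                    n_background_genes = 5L, seed = 9)
  nm <- lognormalize(sim$counts)
  a1 <- transcriptomic_age(sim$counts, sim$ageing_genes, sim$sample_of,
                           sim$sample_ages, normalized = nm)
  rescaled <- nm * 3 + 2   # per-gene affine change washes out in z-scores
  a2 <- transcriptomic_age(sim$counts, sim$ageing_genes, sim$sample_of,
                           sim$sample_ages, normalized = rescaled)
  expect_equal(a1$ages$transcriptomic_age, a2$ages$transcriptomic_age,
               tolerance = 1e-10)
})

test_that("planted ageing factor is recovered (smoke scale)", {
  sim <- simulate_ageing_expression(n_cells = 200L, seed = 19)
  out <- transcriptomic_age(sim$counts, sim$ageing_genes, sim$sample_of,
                            sim$sample_ages)
  rho <- cor(out$ages$transcriptomic_age, sim$truth$ageing_factor,
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("LCS-gene association combines F, P and Spearman thresholds", {
  set.seed(12)
  n <- 150L
  scores <- setNames(runif(n, 1e4, 1e7), paste0("c", 1:n))
  expr <- rbind(
    linear = 2 + 3e-7 * scores,                 # deterministic in the score
    flat = rep(1, n),                            # constant -> skipped
    noise = rnorm(n))
  colnames(expr) <- names(scores)
  out <- suppressWarnings(lcs_gene_assoc(expr, scores))  # perfect-fit warning
  expect_false("flat" %in% out$gene_id)
  lin <- out[out$gene_id == "linear", ]
  expect_true(lin$pass)
  expect_lt(lin$p_value, 1e-10)
  expect_equal(abs(lin$rho), 1)
})

test_that("null genes pass the association filter at below the 1% level", {
  set.seed(13)
  n_cells <- 300L; n_genes <- 1000L
  scores <- setNames(runif(n_cells, 1e4, 1e7), paste0("c", 1:n_cells))
  expr <- matrix(rnorm(n_genes * n_cells), nrow = n_genes,
                 dimnames = list(paste0("g", 1:n_genes), names(scores)))
  out <- lcs_gene_assoc(expr, scores)
  expect_lt(mean(out$pass), 0.02)  # 3-sigma above the nominal 1%
})
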