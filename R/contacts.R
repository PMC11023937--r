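#' Bin scheme for contact maps
#'
#' Half-open bins `[start, end)` on 0-based coordinates; bin 1 starts at
#' `start`.
#'
#' @param chrom Chromosome name.
#' @param end End coordinate (exclusive).
#' @param resolution Bin width in bp.
#' @param start Start coordinate (default 0).
#' @return A `bin_scheme` list with `n_bins`.
#' @export
bin_scheme <- function(chrom, end, resolution, start = 0) {
  structure(list(chrom = chrom, start = start, end = end,
                 resolution = resolution,
                 n_bins = as.integer(ceiling((end - start) / resolution))),
            class = "bin_scheme")
}

.bin_of <- function(pos, scheme) {
  b <- (pos - scheme$start) %/% scheme$resolution + 1L
  b[pos < scheme$start | pos >= scheme$end] <- NA_integer_
  as.integer(b)
}

#' Cluster-size classes used for stratified contact maps
#'
#' small = 2-10 reads, medium = 11-50, large = 51-100.
#'
#' @param name One of "small", "medium", "large".
#' @return Integer range `c(lo, hi)`.
#' @export
size_class_range <- function(name) {
  switch(name,
         small = c(2L, 10L), medium = c(11L, 50L), large = c(51L, 100L),
         stop("unknown size class: ", name))
}

#' Binned DNA-DNA contact matrix
#'
#' Sums decomposed pair weights into upper-triangular bins. Contacts outside
#' the scheme are dropped and counted.
#'
#' @param contacts WeightedContact tibble ([decompose_contacts()]).
#' @param scheme A [bin_scheme()].
#' @param size_class Optional "small"/"medium"/"large" (or an integer range)
#'   filter on `cluster_size`.
#' @return A `music_matrix`: list with sparse `tbl` (`bin_i <= bin_j`,
#'   `weight`), the `scheme`, `total_weight` and `n_dropped`.
#' @export
contact_matrix <- function(contacts, scheme, size_class = NULL) {
  if (!is.null(size_class)) {
    rng <- if (is.character(size_class)) size_class_range(size_class) else size_class
    contacts <- filter(contacts, .data$cluster_size >= rng[1],
                       .data$cluster_size <= rng[2])
  }
  in_chrom <- contacts$chrom_a == scheme$chrom &
    contacts$chrom_b == scheme$chrom
  bi <- .bin_of(contacts$pos_a, scheme)
  bj <- .bin_of(contacts$pos_b, scheme)
  ok <- in_chrom & !is.na(bi) & !is.na(bj)
  tbl <- tibble(bin_i = pmin(bi[ok], bj[ok]), bin_j = pmax(bi[ok], bj[ok]),
                weight = contacts$weight[ok]) |>
    group_by(.data$bin_i, .data$bin_j) |>
    summarise(weight = sum(.data$weight), .groups = "drop")
  structure(list(tbl = tbl, scheme = scheme,
                 total_weight = sum(tbl$weight),
                 n_dropped = sum(!ok)),
            class = "music_matrix")
}

#' Dense symmetric matrix from a sparse contact matrix
#'
#' @param m A `music_matrix`.
#' @return Numeric `n_bins x n_bins` symmetric matrix.
#' @export
as_dense_matrix <- function(m) {
  n <- m$scheme$n_bins
  out <- matrix(0, n, n)
  idx <- cbind(m$tbl$bin_i, m$tbl$bin_j)
  out[idx] <- m$tbl$weight
  out[idx[, c(2, 1), drop = FALSE]] <- m$tbl$weight
  out
}

#' Visualization transform for contact maps
#'
#' Entrywise `log10(1 + factor * w)`: the linear scale-up avoids taking logs
#' of sub-unit weights, the log compresses the dynamic range. Monotone in
#' `w`, zero at zero.
#'
#' @param m A `music_matrix` or plain numeric matrix.
#' @param factor Linear scale-up (typically 100 or 1000).
#' @return Same shape as the input with transformed weights.
#' @export
visual_transform <- function(m, factor = 100) {
  if (inherits(m, "music_matrix")) {
    m$tbl$weight <- log10(1 + factor * m$tbl$weight)
    m$total_weight <- sum(m$tbl$weight)
    m
  } else {
    log10(1 + factor * m)
  }
}

#' Normalize a pair of contact maps to a common [0, 1] scale
#'
#' Each map is log-scaled then divided by its own maximum, so both maps end
#' up in `[0, 1]` with max exactly 1 (unless all-zero, which warns and stays
#' zero).
#'
#' @param a,b Dense numeric matrices.
#' @param factor Linear scale-up before the log.
#' @return List of the two normalized matrices.
#' @export
normalize_map_pair <- function(a, b, factor = 100) {
  norm1 <- function(x) {
    lx <- log10(1 + factor * x)
    mx <- max(lx)
    if (mx == 0) {
      warning("all-zero contact map; returning zeros")
      lx
    } else lx / mx
  }
  list(a = norm1(a), b = norm1(b))
}

#' Contact frequency versus genomic distance
#'
#' The distance range `[s_min, s_max]` (default 10 bp to 150 Mb) is divided
#' into `n_bins` equal-width bins. Intrachromosomal pair weights are summed
#' per distance bin; with `mode = "per_cell_then_sum"` each cell's curve is
#' normalized to unit mass before aggregation, with `"pool_all"` weights are
#' pooled directly.
#'
#' @param contacts WeightedContact tibble.
#' @param arms Optional tibble (`chrom`, `arm_boundary`); when given, both
#'   ends must fall in the same chromosomal arm.
#' @param n_bins Number of equal-width distance bins.
#' @param s_min,s_max Distance range in bp; pairs outside are excluded and
#'   counted.
#' @param mode Aggregation mode.
#' @return A `music_pc_curve`: sparse tibble (`bin`, `s_mid`, `freq`) with
#'   the binning metadata as attributes.
#' @export
pc_curve <- function(contacts, arms = NULL, n_bins = 5e5, s_min = 10,
                     s_max = 1.5e8, mode = c("per_cell_then_sum", "pool_all")) {
  mode <- match.arg(mode)
  cc <- filter(contacts, .data$chrom_a == .data$chrom_b)
  if (!is.null(arms)) {
    cc <- cc |>
      left_join(arms, by = c(chrom_a = "chrom")) |>
      filter((.data$pos_a < .data$arm_boundary) ==
               (.data$pos_b < .data$arm_boundary)) |>
      select(-"arm_boundary")
  }
  d <- abs(cc$pos_a - cc$pos_b)
  inside <- d >= s_min & d <= s_max
  n_excluded <- sum(!inside)
  cc <- cc[inside, ]
  d <- d[inside]
  width <- (s_max - s_min) / n_bins
  bin <- pmin(as.integer((d - s_min) %/% width) + 1L, as.integer(n_bins))
  df <- tibble(cell_id = cc$cell_id, bin = bin, weight = cc$weight)
  if (mode == "per_cell_then_sum") {
    df <- df |>
      group_by(.data$cell_id) |>
      mutate(weight = .data$weight / sum(.data$weight)) |>
      ungroup()
  }
  out <- df |>
    group_by(.data$bin) |>
    summarise(freq = sum(.data$weight), .groups = "drop") |>
    mutate(s_mid = s_min + (.data$bin - 0.5) * width) |>
    select("bin", "s_mid", "freq")
  structure(out, class = c("music_pc_curve", class(out)),
            n_bins = n_bins, s_min = s_min, s_max = s_max, width = width,
            n_excluded = n_excluded, mode = mode)
}

#' Fit the log-log slope of a distance-decay curve
#'
#' Aggregates the fine linear bins into log-spaced windows (frequency per bp)
#' and regresses `log10(freq density)` on `log10(distance)` over `s_range`.
#'
#' @param curve A [pc_curve()] result.
#' @param s_range Distance range used for the fit.
#' @param n_logbins Number of log-spaced windows.
#' @return The fitted slope (for contacts generated with `p(s) ~ s^-alpha`
#'   the slope estimates `-alpha`).
#' @export
fit_pc_slope <- function(curve, s_range = c(1e4, 1e7), n_logbins = 25L) {
  edges <- 10^seq(log10(s_range[1]), log10(s_range[2]),
                  length.out = n_logbins + 1L)
  df <- curve |>
    filter(.data$s_mid >= s_range[1], .data$s_mid <= s_range[2]) |>
    mutate(lb = findInterval(.data$s_mid, edges, rightmost.closed = TRUE)) |>
    group_by(.data$lb) |>
    summarise(freq = sum(.data$freq), .groups = "drop") |>
    mutate(dens = .data$freq / (edges[.data$lb + 1L] - edges[.data$lb]),
           x = sqrt(edges[.data$lb] * edges[.data$lb + 1L])) |>
    filter(.data$freq > 0)
  stats::coef(lm(log10(dens) ~ log10(x), data = df))[[2]]
}

#' Log-spaced distance-bin edges
#'
#' 151 edges for 150 bins, the n-th bin spanning
#' `[2^(log2(5000) + step (n-1)), 2^(log2(5000) + step n))` with
#' `step = (log2(1.5e8) - log2(5000)) / 150`; first edge 5,000 bp, last
#' 1.5e8 bp.
#'
#' @param n_bins Number of bins.
#' @param s_min,s_max First and last edge in bp.
#' @return Numeric vector of length `n_bins + 1`.
#' @export
logbin_edges <- function(n_bins = 150L, s_min = 5000, s_max = 1.5e8) {
  step <- (log2(s_max) - log2(s_min)) / n_bins
  2^(log2(s_min) + step * (0:n_bins))
}

#' Per-cell log-binned distance profile
#'
#' For each cell, intrachromosomal pair weights are accumulated into the
#' [logbin_edges()] bins, divided by bin width (frequency per bp), then
#' normalized to unit sum within the cell. Cells with no in-range contact
#' are omitted.
#'
#' @param contacts WeightedContact tibble.
#' @param edges Bin edges.
#' @return A `music_logbin_profile` tibble: `cell_id`, `bin`, `s_lo`,
#'   `s_hi`, `value`; per cell the values sum to 1.
#' @export
logbin_profile <- function(contacts, edges = logbin_edges()) {
  cc <- filter(contacts, .data$chrom_a == .data$chrom_b)
  d <- abs(cc$pos_a - cc$pos_b)
  inside <- d >= edges[1] & d <= edges[length(edges)]
  cc <- cc[inside, ]; d <- d[inside]
  bin <- pmin(findInterval(d, edges), length(edges) - 1L)
  width <- diff(edges)
  out <- tibble(cell_id = cc$cell_id, bin = bin, weight = cc$weight) |>
    group_by(.data$cell_id, .data$bin) |>
    summarise(freq = sum(.data$weight), .groups = "drop") |>
    mutate(dens = .data$freq / width[.data$bin]) |>
    group_by(.data$cell_id) |>
    mutate(value = .data$dens / sum(.data$dens)) |>
    ungroup() |>
    mutate(s_lo = edges[.data$bin], s_hi = edges[.data$bin + 1L]) |>
    select("cell_id", "bin", "s_lo", "s_hi", "value")
  structure(out, class = c("music_logbin_profile", class(out)),
            edges = edges)
}

#' Compartment (PC1) score of a contact matrix
#'
#' Observed/expected ratio (expected = distance-stratified mean over
#' informative bins), correlation matrix, first eigenvector. The sign is
#' oriented to correlate positively with `reference` when given (PC1 sign is
#' otherwise arbitrary).
#'
#' @param m A `music_matrix` or dense symmetric matrix.
#' @param reference Optional numeric orientation vector (e.g. gene density).
#' @param min_bins Minimum number of informative bins.
#' @return Numeric PC1 vector (NA at uninformative bins).
#' @export
compartment_track <- function(m, reference = NULL, min_bins = 10L) {
  obs <- if (inherits(m, "music_matrix")) as_dense_matrix(m) else m
  n <- nrow(obs)
  info <- which(rowSums(obs) > 0)
  if (length(info) < min_bins) {
    stop("fewer than ", min_bins, " informative bins")
  }
  o <- obs[info, info]
  k <- length(info)
  dist_idx <- abs(row(o) - col(o))
  expd <- vapply(0:(k - 1), function(d) mean(o[dist_idx == d]), numeric(1))
  e <- matrix(expd[dist_idx + 1L], k, k)
  oe <- o / e
  oe[!is.finite(oe)] <- NA
  cm <- suppressWarnings(cor(oe, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  if (all(abs(cm - cm[1, 1]) < 1e-12)) {
    stop("degenerate matrix: correlation structure is flat, PC1 undefined")
  }
  pc1 <- eigen(cm, symmetric = TRUE)$vectors[, 1]
  out <- rep(NA_real_, n)
  out[info] <- pc1
  if (!is.null(reference)) {
    r <- suppressWarnings(cor(out, reference, use = "pairwise.complete.obs"))
    if (!is.na(r) && r < 0) out <- -out
  }
  out
}

#' Compare two compartment tracks across chromosomes
#'
#' @param a,b Named lists of PC1 vectors (names = chromosomes).
#' @return List: `per_chrom` tibble of Pearson r, `median_r`.
#' @export
compare_compartments <- function(a, b) {
  chroms <- intersect(names(a), names(b))
  per <- tibble(
    chrom = chroms,
    r = vapply(chroms, function(ch)
      suppressWarnings(cor(a[[ch]], b[[ch]], use = "pairwise.complete.obs")),
      numeric(1)))
  list(per_chrom = per, median_r = median(per$r, na.rm = TRUE))
}
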