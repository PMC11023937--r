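#' Strand-aware promoter intervals from the annotation
#'
#' The promoter of a gene is the closed interval TSS +/- `flank` (TSS is the
#' gene start on "+", the gene end on "-").
#'
#' @param ref A [make_reference()] object.
#' @param flank Flanking distance in bp.
#' @return Tibble: `gene_id`, `chrom`, `tss`, `prom_start`, `prom_end`
#'   (1-based closed).
#' @export
promoters_from_reference <- function(ref, flank = 2500L) {
  ref$genes |>
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end),
           prom_start = pmax(1L, .data$tss - flank),
           prom_end = .data$tss + flank) |>
    select("gene_id", "chrom", "tss", "prom_start", "prom_end")
}

#' Flag contacts supporting eQTL-target pairs
#'
#' A DNA-DNA contact supports an eQTL-target pair when one end overlaps the
#' variant position (a 1-bp interval; at least one base) and the other end
#' overlaps the target promoter (TSS +/- `flank`, closed); both end
#' assignments are tried. Contact ends are fragments `[pos, pos + frag_len)`
#' on 0-based coordinates; eQTL positions are 1-based input.
#'
#' @param contacts WeightedContact tibble with `pos_a`/`pos_b` and
#'   `frag_len_a`/`frag_len_b` columns (defaulting to 1 bp when absent).
#' @param pairs eQTL tibble: `eqtl_id`, `chrom`, `pos` (1-based), `gene_id`,
#'   `tss` (1-based), plus any metadata.
#' @param flank Promoter flank in bp.
#' @return Tibble: one row per (contact row, supported pair):
#'   `contact_idx`, `eqtl_id`, `gene_id`.
#' @export
supporting_contacts <- function(contacts, pairs, flank = 2500L) {
  n <- nrow(contacts)
  fa <- contacts[["frag_len_a"]] %||% rep(1L, n)
  fb <- contacts[["frag_len_b"]] %||% rep(1L, n)
  # closed 1-based end intervals
  ends <- tibble(
    contact_idx = rep(seq_len(n), 2L),
    end = rep(c("a", "b"), each = n),
    chrom = c(contacts$chrom_a, contacts$chrom_b),
    lo = c(contacts$pos_a + 1L, contacts$pos_b + 1L),
    hi = c(contacts$pos_a + fa, contacts$pos_b + fb))
  hit_var <- .overlap_join(ends, tibble(chrom = pairs$chrom, lo = pairs$pos,
                                        hi = pairs$pos, idx = seq_len(nrow(pairs))))
  hit_prom <- .overlap_join(ends, tibble(chrom = pairs$chrom,
                                         lo = pmax(1L, pairs$tss - flank),
                                         hi = pairs$tss + flank,
                                         idx = seq_len(nrow(pairs))))
  sup <- inner_join(hit_var, hit_prom, by = c("contact_idx", "idx"),
                    relationship = "many-to-many") |>
    filter(.data$end.x != .data$end.y) |>
    distinct(.data$contact_idx, .data$idx)
  tibble(contact_idx = sup$contact_idx,
         eqtl_id = pairs$eqtl_id[sup$idx],
         gene_id = pairs$gene_id[sup$idx])
}

# interval overlap join via IRanges
.overlap_join <- function(x, y) {
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$lo, x$hi)),
    GenomicRanges::GRanges(y$chrom, IRanges::IRanges(y$lo, y$hi)))
  tibble(contact_idx = x$contact_idx[S4Vectors::queryHits(hits)],
         end = x$end[S4Vectors::queryHits(hits)],
         idx = y$idx[S4Vectors::subjectHits(hits)])
}

#' Filter an eQTL table per the study's inclusion rules
#'
#' Keeps pairs with nominal P below `p_max` and drops excluded cell types.
#'
#' @param pairs eQTL tibble with `p_nominal` and `cell_type`.
#' @param p_max Nominal-P threshold.
#' @param drop_types Cell types removed entirely.
#' @return Filtered tibble.
#' @export
filter_eqtl_pairs <- function(pairs, p_max = 1e-4,
                              drop_types = c("Endothelial", "Pericyte")) {
  filter(pairs, .data$p_nominal < p_max, !.data$cell_type %in% drop_types)
}

#' Cross-tabulate supporting contacts by cell type
#'
#' Rows are the contact's cell type (type label of the contact's cell of
#' origin; contacts from unassigned cells are excluded), columns the eQTL
#' pair's cell type. In CTS mode only pairs exclusive to a single cell type
#' are used.
#'
#' @param support Output of [supporting_contacts()], joined with
#'   `contact_type` (cell type of the contact) and `eqtl_type` columns.
#' @param types The cell-type universe (default: union of observed).
#' @return A `music_support_table`: the `r x r` contingency matrix.
#' @export
build_support_table <- function(support,
                                types = sort(union(support$contact_type,
                                                   support$eqtl_type))) {
  support <- filter(support, !is.na(.data$contact_type),
                    !is.na(.data$eqtl_type))
  tab <- table(factor(support$contact_type, levels = types),
               factor(support$eqtl_type, levels = types))
  structure(unclass(tab), class = c("music_support_table", "matrix"),
            dimnames = dimnames(tab))
}

#' Global chi-square test and per-type odds ratios
#'
#' Pearson chi-square on the full `r x c` table (df = (r-1)(c-1)); each cell
#' type's 2 x 2 reduction (contact type is/is not A x pair type is/is not A)
#' yields OR = ad/bc with `SELOR = sqrt(1/a + 1/b + 1/c + 1/d)` and the 95%
#' CI `exp(log(OR) +/- 1.96 SELOR)`. Any zero cell triggers the
#' Haldane-Anscombe +0.5 correction (flagged).
#'
#' @param table A [build_support_table()] matrix.
#' @return A `music_assoc` list: `chisq` (statistic, df, p_value),
#'   `by_type` tibble (a, b, c, d, OR, SELOR, CI, corrected, per-type
#'   chi-square P), `table`.
#' @export
chisq_and_or <- function(table) {
  if (sum(table) == 0) stop("empty support table; test refused")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("some expected counts are below 5; chi-square may be unreliable")
  }
  types <- rownames(table)
  by_type <- dplyr::bind_rows(lapply(types, function(tp) {
    a <- table[tp, tp]
    b <- sum(table[tp, ]) - a
    cc <- sum(table[, tp]) - a
    d <- sum(table) - a - b - cc
    corrected <- any(c(a, b, cc, d) == 0)
    if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    or <- (a * d) / (b * cc)
    selor <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    m2 <- matrix(c(a, cc, b, d), 2)
    p2 <- suppressWarnings(chisq.test(m2, correct = FALSE))$p.value
    tibble(cell_type = tp, a = a, b = b, c = cc, d = d,
           odds_ratio = or, selor = selor,
           ci_lo = exp(log(or) - 1.96 * selor),
           ci_hi = exp(log(or) + 1.96 * selor),
           corrected = corrected, p_value = p2)
  }))
  structure(list(
    chisq = list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value),
    by_type = by_type, table = table), class = "music_assoc")
}

#' @export
print.music_assoc <- function(x, ...) {
  cat(sprintf("Global chi-square: X2 = %.3f, df = %d, P = %.3g\n",
              x$chisq$statistic, x$chisq$df, x$chisq$p_value))
  print(dplyr::select(x$by_type, "cell_type", "odds_ratio", "ci_lo",
                      "ci_hi", "p_value"))
  invisible(x)
}

#' Simulate supporting-contact / eQTL cell-type data
#'
#' Generative model for calibration and power checks: each supporting
#' contact is attached to an eQTL pair whose cell type is uniform over the
#' type universe; the contact's own cell type matches the pair's type with
#' odds `enrichment` relative to each mismatching type. Under this model the
#' per-type true odds ratio is `enrichment * (enrichment + k - 2) / (k - 1)`
#' for `k` types (= K(K+4)/5 for the 6-type set).
#'
#' @param n_contacts Number of supporting contacts.
#' @param enrichment Match odds K (1 = null).
#' @param types Cell-type universe.
#' @param seed Integer seed.
#' @return List: `support` tibble (`contact_type`, `eqtl_type`), `true_or`.
#' @export
simulate_eqtl_support <- function(n_contacts, enrichment = 1,
                                  types = c("Ast", "ExN", "InN", "Mic",
                                            "Oli", "Opc"),
                                  seed = 1L) {
  withr_seed(seed)
  k <- length(types)
  eqtl_type <- sample(types, n_contacts, replace = TRUE)
  contact_type <- vapply(eqtl_type, function(tp) {
    p <- rep(1, k); p[types == tp] <- enrichment
    sample(types, 1L, prob = p)
  }, character(1))
  true_or <- enrichment * (enrichment + k - 2) / (k - 1)
  list(support = tibble(contact_type = contact_type, eqtl_type = eqtl_type),
       true_or = true_or)
}
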