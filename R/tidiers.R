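#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-type association results
#'
#' @param x A [chisq_and_or()] fit.
#' @param ... Unused.
#' @return Tibble with one row per cell type: odds ratio, CI, P.
#' @export
tidy.music_assoc <- function(x, ...) {
  dplyr::select(x$by_type, "cell_type", "odds_ratio", "ci_lo", "ci_hi",
                "p_value", "corrected")
}

#' One-row summary of the global association test
#'
#' @param x A [chisq_and_or()] fit.
#' @param ... Unused.
#' @return One-row tibble: statistic, df, p.value, n.
#' @export
glance.music_assoc <- function(x, ...) {
  tibble(statistic = x$chisq$statistic, df = x$chisq$df,
         p.value = x$chisq$p_value, n = sum(x$table))
}

#' Tidy a cluster census
#'
#' @param x A [census()] object.
#' @param ... Unused.
#' @return The by-class tibble (type, size class, counts, percentages).
#' @export
tidy.music_census <- function(x, ...) x$by_class

#' One-row-per-type census totals
#'
#' @param x A [census()] object.
#' @param ... Unused.
#' @return The totals tibble.
#' @export
glance.music_census <- function(x, ...) x$totals
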