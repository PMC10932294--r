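#' Hypergeometric over-representation analysis
#'
#' Exact one-sided over-representation test of a selected protein list
#' against annotation sets. For a universe of size `N`, an annotation set
#' covering `m` universe proteins, `k` selected proteins and an observed
#' overlap `x`, the p-value is the upper-tail hypergeometric probability of
#' an overlap at least as large:
#' \deqn{p = \sum_{j \ge x} \frac{\binom{m}{j}\binom{N-m}{k-j}}{\binom{N}{k}}}
#' P-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param selected Character vector of selected protein ids (must be a
#'   subset of `universe`).
#' @param annotation_sets Named list of character vectors (set id ->
#'   member proteins); each set is intersected with the universe first.
#' @param universe Character vector of all assayable protein ids.
#' @return Tibble with columns `set`, `set_size`, `overlap`, `expected`,
#'   `p_value`, `adj_p_value`, sorted by `p_value`.
#' @examples
#' ora_enrichment(c("a", "b"), list(S1 = c("a", "b", "c")), letters[1:10])
#' @export
ora_enrichment <- function(selected, annotation_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  selected <- unique(selected)
  if (!all(selected %in% universe)) {
    abort("`selected` must be a subset of `universe`.")
  }
  if (!is.list(annotation_sets) || is.null(names(annotation_sets))) {
    abort("`annotation_sets` must be a named list of protein id vectors.")
  }
  N <- length(universe)
  k <- length(selected)
  res <- purrr::imap_dfr(annotation_sets, function(members, id) {
    members <- intersect(unique(members), universe)
    m <- length(members)
    x <- length(intersect(selected, members))
    tibble::tibble(
      set = id,
      set_size = m,
      overlap = x,
      expected = k * m / N,
      p_value = phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    )
  })
  res$adj_p_value <- bh_adjust(res$p_value)
  dplyr::arrange(res, .data$p_value, .data$set)
}
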