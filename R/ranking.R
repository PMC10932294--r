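#' Rank network nodes by a weighted sum of normalized centralities
#'
#' Each centrality is min-max normalized to `[0, 1]` across nodes before
#' weighting, so count-scaled metrics (degree, stress) and fraction-scaled
#' metrics (betweenness, closeness) mix on a common footing. Eccentricity
#' is inverted before normalization by default (a peripheral node - high
#' eccentricity - contributes less). A metric that is constant across nodes
#' normalizes to 1 for every node (in particular, a single-node network
#' scores the full weight sum). The default weights respect the ordering
#' degree = stress > betweenness > closeness > eccentricity.
#'
#' @param centralities Tibble from [compute_centralities()].
#' @param weights Named nonnegative weights for `degree`, `stress`,
#'   `betweenness`, `closeness`, `eccentricity`; not all zero.
#' @param invert_eccentricity Treat low eccentricity as central (default
#'   `TRUE`).
#' @return A `target_ranking` tibble: the input metrics, their normalized
#'   versions (`norm_*`), `score` and `rank` (descending score, ties broken
#'   lexicographically by node id).
#' @export
weighted_rank <- function(centralities,
                          weights = c(degree = 0.28, stress = 0.28,
                                      betweenness = 0.20, closeness = 0.14,
                                      eccentricity = 0.10),
                          invert_eccentricity = TRUE) {
  metrics <- c("degree", "stress", "betweenness", "closeness", "eccentricity")
  centralities <- tibble::as_tibble(centralities)
  if (!all(c("node", metrics) %in% names(centralities))) {
    abort("`centralities` must come from compute_centralities().")
  }
  if (!all(metrics %in% names(weights))) {
    abort(sprintf("`weights` must name all of: %s.",
                  paste(metrics, collapse = ", ")))
  }
  weights <- weights[metrics]
  if (any(weights < 0) || all(weights == 0)) {
    abort("Weights must be nonnegative and not all zero.")
  }
  minmax <- function(x, invert = FALSE) {
    x <- as.numeric(x)
    if (invert) x <- -x
    if (all(is.na(x))) return(rep(1, length(x)))
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (!is.finite(lo) || hi == lo) return(rep(1, length(x)))
    out <- (x - lo) / (hi - lo)
    out[is.na(out)] <- 0
    out
  }
  norm <- purrr::map(setNames(metrics, metrics), function(m) {
    minmax(centralities[[m]], invert = (m == "eccentricity") && invert_eccentricity)
  })
  score <- Reduce(`+`, purrr::imap(norm, function(v, m) weights[[m]] * v))
  out <- centralities
  for (m in metrics) out[[paste0("norm_", m)]] <- norm[[m]]
  out$score <- score
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$node)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("target_ranking", class(out))
  attr(out, "weights") <- weights
  out
}

#' Select high-fold-change drug-target candidates
#'
#' Filters the weighted centrality ranking to nodes whose measured protein
#' fold change passes the two-sided threshold
#' (`|log2 FC| >= log2(fc_min)`), takes the top `top_k` by weighted score,
#' produces a second top-`top_k` list from the PageRank ordering the same
#' way, and reports the union with provenance flags (`"weighted"`,
#' `"pagerank"`, or `"both"`). Nodes without a fold-change entry are
#' excluded with a warning.
#'
#' @param ranking A `target_ranking` from [weighted_rank()].
#' @param fold_changes Named numeric vector (node -> linear fold change) or
#'   a tibble with columns `node`/`protein` and `fold_change`.
#' @param pagerank Optional tibble from [ppin_pagerank()]; when omitted the
#'   PageRank list is skipped.
#' @param fc_min Linear fold-change threshold (default 1.5).
#' @param top_k List length (default 10).
#' @return Tibble: `node`, `fold_change`, `score`, `weighted_rank`,
#'   `pagerank`, `pagerank_rank`, `source`, ordered by weighted rank then
#'   PageRank rank.
#' @export
select_targets <- function(ranking, fold_changes, pagerank = NULL,
                           fc_min = 1.5, top_k = 10) {
  stopifnot(inherits(ranking, "target_ranking"))
  assert_scalar_number(fc_min, "fc_min", lower = 1)
  top_k <- assert_count(top_k, "top_k")
  if (is.data.frame(fold_changes)) {
    id_col <- intersect(c("node", "protein"), names(fold_changes))[1]
    if (is.na(id_col) || !"fold_change" %in% names(fold_changes)) {
      abort("`fold_changes` needs a node/protein column and `fold_change`.")
    }
    fold_changes <- setNames(fold_changes$fold_change, fold_changes[[id_col]])
  }
  if (any(fold_changes <= 0, na.rm = TRUE)) {
    abort("Fold changes must be positive linear ratios.")
  }

  nodes <- ranking$node
  missing_fc <- setdiff(nodes, names(fold_changes))
  if (length(missing_fc) > 0) {
    warn(sprintf("%d node(s) have no fold-change entry (e.g. '%s'); excluded.",
                 length(missing_fc), missing_fc[1]))
  }
  fc <- fold_changes[nodes]
  pass <- !is.na(fc) & abs(log2(fc)) >= log2(fc_min)

  eligible <- ranking[pass, c("node", "score", "rank")]
  top_weighted <- utils::head(eligible$node, top_k)

  top_pr <- character(0)
  pr_tbl <- NULL
  if (!is.null(pagerank)) {
    pr_tbl <- tibble::as_tibble(pagerank)
    pr_el <- pr_tbl[pr_tbl$node %in% nodes[pass], ]
    pr_el <- dplyr::arrange(pr_el, dplyr::desc(.data$pagerank), .data$node)
    pr_el$pagerank_rank <- seq_len(nrow(pr_el))
    top_pr <- utils::head(pr_el$node, top_k)
  }

  union_nodes <- union(top_weighted, top_pr)
  out <- tibble::tibble(
    node = union_nodes,
    fold_change = unname(fold_changes[union_nodes]),
    score = ranking$score[match(union_nodes, ranking$node)],
    weighted_rank = ranking$rank[match(union_nodes, ranking$node)],
    source = dplyr::case_when(
      union_nodes %in% top_weighted & union_nodes %in% top_pr ~ "both",
      union_nodes %in% top_weighted ~ "weighted",
      .default = "pagerank"
    )
  )
  if (!is.null(pr_tbl)) {
    out$pagerank <- pr_tbl$pagerank[match(out$node, pr_tbl$node)]
    out$pagerank_rank <- pr_el$pagerank_rank[match(out$node, pr_el$node)]
  }
  dplyr::arrange(out, .data$weighted_rank)
}
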