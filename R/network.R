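#' Build a confidence-thresholded protein-protein interaction network
#'
#' Constructs an undirected simple graph from a STRING-style edge list,
#' keeping only interactions whose combined confidence strictly exceeds the
#' threshold (high-confidence interactions at the conventional 0.7 cutoff).
#' Duplicate edges (in either orientation) collapse to one edge with the
#' maximum confidence; self-loops are dropped with a warning; nodes left
#' without any retained edge are dropped unless explicitly listed in
#' `nodes`.
#'
#' @param edges Tibble/data frame whose first three columns are protein A,
#'   protein B and a combined confidence score in `[0, 1]`.
#' @param min_confidence Retention threshold (edges must exceed it).
#' @param nodes Optional character vector of node ids to keep even when
#'   isolated.
#' @return An `igraph` undirected graph with edge attribute `confidence`.
#' @export
build_ppin <- function(edges, min_confidence = 0.7, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (ncol(edges) < 3) abort("`edges` needs columns: from, to, confidence.")
  edges <- setNames(edges[1:3], c("from", "to", "confidence"))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(!is.finite(edges$confidence)) ||
      any(edges$confidence < 0 | edges$confidence > 1)) {
    abort("Confidences must lie in [0, 1].")
  }
  assert_scalar_number(min_confidence, "min_confidence", lower = 0, upper = 1)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("Dropping %d self-loop edge(s).", sum(loops)))
    edges <- edges[!loops, ]
  }
  edges <- dplyr::filter(edges, .data$confidence > min_confidence)
  vertices <- if (is.null(nodes)) NULL else {
    data.frame(name = unique(c(nodes, edges$from, edges$to)))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(confidence = "max"))
}

#' Read a STRING-dialect edge list
#'
#' Expects a TSV with columns `protein1`, `protein2`, `combined_score`
#' (or any three columns in that order). STRING exports scores on a
#' 0-1000 scale; scales are auto-detected (maximum score above 1 implies
#' the 0-1000 scale) and rescaled to `[0, 1]` with a message.
#'
#' @param path File path.
#' @return Tibble `from`, `to`, `confidence`.
#' @export
read_string_edges <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(raw) < 3) abort("Edge list needs at least three columns.")
  out <- setNames(raw[1:3], c("from", "to", "confidence"))
  if (max(out$confidence, na.rm = TRUE) > 1) {
    inform("Scores exceed 1; interpreting as STRING 0-1000 scale.")
    out$confidence <- out$confidence / 1000
  }
  tibble::as_tibble(out)
}

#' Node centralities of an interaction network
#'
#' Computes, per node: degree (incident edge count), betweenness (fraction
#' of shortest paths through the node, normalized by `(n-1)(n-2)/2`),
#' closeness (`(n-1) / sum of geodesic distances`), stress (raw count of
#' shortest paths through the node) and eccentricity (maximum geodesic
#' distance). For disconnected graphs every path-based metric is computed
#' within the node's connected component (`n` = component size), matching
#' the behavior of common network-analysis tools for undirected networks.
#'
#' @param network An `igraph` graph (see [build_ppin()]).
#' @return Tibble: `node`, `component`, `degree`, `betweenness`,
#'   `closeness`, `stress`, `eccentricity`. Isolated nodes get closeness
#'   `NA` and eccentricity 0.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' compute_centralities(g)
#' @export
compute_centralities <- function(network) {
  if (igraph::vcount(network) == 0) abort("Network is empty.")
  comps <- igraph::components(network)
  out <- purrr::map_dfr(seq_len(comps$no), function(ci) {
    members <- names(comps$membership)[comps$membership == ci]
    sub <- igraph::induced_subgraph(network, members)
    n <- igraph::vcount(sub)
    deg <- igraph::degree(sub)
    if (n == 1) {
      return(tibble::tibble(node = members, component = ci, degree = 0L,
                            betweenness = 0, closeness = NA_real_,
                            stress = 0L, eccentricity = 0))
    }
    btw_raw <- igraph::betweenness(sub, directed = FALSE)
    btw <- if (n > 2) btw_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
    d <- igraph::distances(sub)
    tibble::tibble(
      node = igraph::V(sub)$name,
      component = ci,
      degree = as.integer(deg),
      betweenness = unname(btw),
      closeness = unname((n - 1) / rowSums(d)),
      stress = as.integer(stress_centrality(sub)),
      eccentricity = unname(apply(d, 1, max))
    )
  })
  dplyr::arrange(out, .data$node)
}

#' Stress centrality (shortest-path counts through each node)
#'
#' Stress of node `v` is the number of shortest paths between all ordered-
#' independent pairs `s < t` (both distinct from `v`) that pass through
#' `v`: \eqn{\sum_{s<t} \sigma_{st}(v)}. Computed from all-pairs geodesic
#' path counts obtained by breadth-first search from every node.
#'
#' @param network A connected or disconnected `igraph` graph (pairs in
#'   different components contribute nothing).
#' @return Named integer vector of stress values.
#' @export
stress_centrality <- function(network) {
  n <- igraph::vcount(network)
  nodes <- igraph::V(network)$name %||% as.character(seq_len(n))
  if (n <= 2) return(setNames(rep(0L, n), nodes))
  d <- igraph::distances(network)
  adj <- igraph::as_adj_list(network)
  # sigma[s, v]: number of geodesics from s to v.
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (v in reach[order(d[s, reach])]) {
      if (v == s) next
      pred <- as.integer(adj[[v]])
      pred <- pred[d[s, pred] == d[s, v] - 1]
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  stress <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      if (s == v) next
      for (t in seq(s + 1, n)) {
        if (t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          stress[v] <- stress[v] + sigma[s, v] * sigma[v, t]
        }
      }
    }
  }
  setNames(as.integer(stress), nodes)
}

#' PageRank scores of an interaction network
#'
#' Stationary distribution of the damped random walk on the undirected
#' graph (each edge walkable in both directions). Scores over the whole
#' graph sum to 1.
#'
#' @param network An `igraph` graph.
#' @param damping Damping factor (default 0.85).
#' @return Tibble `node`, `pagerank`, sorted by decreasing score (ties
#'   broken by node id).
#' @export
ppin_pagerank <- function(network, damping = 0.85) {
  if (igraph::vcount(network) == 0) abort("Network is empty.")
  pr <- igraph::page_rank(network, damping = damping, algo = "prpack")$vector
  tibble::tibble(node = names(pr), pagerank = unname(pr)) |>
    dplyr::arrange(dplyr::desc(.data$pagerank), .data$node)
}
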