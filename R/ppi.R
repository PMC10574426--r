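#' Build a PPI graph from a confidence-scored edge table
#'
#' Keeps edges whose combined confidence score is strictly greater than
#' `min_score` (the usual highest-confidence cutoff is 0.9) and returns a
#' simple undirected graph. Scores may be on the 0–1 or 0–1000 scale; the
#' scale is auto-detected (any score above 1.5 implies the 0–1000 scale)
#' and divided down. Nodes with no surviving edge are retained only when
#' listed in an explicit `nodes` universe.
#'
#' @param edges Data frame whose first two columns are node names, with a
#'   score column named `combined_score` or `score` (case-insensitive;
#'   otherwise the third column is used).
#' @param min_score Strict confidence cutoff (default 0.9).
#' @param nodes Optional character vector: node universe whose members are
#'   kept as isolated vertices even without surviving edges.
#' @return An `igraph` object (undirected, simple).
#' @examples
#' tbl <- tibble::tibble(node1 = c("A", "A"), node2 = c("B", "C"),
#'                       combined_score = c(0.95, 0.85))
#' igraph::ecount(graph_from_string_edges(tbl))
#' @export
graph_from_string_edges <- function(edges, min_score = 0.9, nodes = NULL) {
  edges <- as_tibble(edges)
  if (ncol(edges) < 3) abort("edge table needs two node columns and a score")
  score_col <- intersect(c("combined_score", "score"),
                         tolower(names(edges)))[1]
  score_idx <- if (!is.na(score_col)) match(score_col, tolower(names(edges))) else 3L
  n1 <- as.character(edges[[1]]); n2 <- as.character(edges[[2]])
  sc <- suppressWarnings(as.numeric(edges[[score_idx]]))
  bad <- which(is.na(n1) | is.na(n2) | n1 == "" | n2 == "" | is.na(sc))
  if (length(bad) > 0) {
    abort(paste0("malformed edge row(s): ", paste(bad, collapse = ", ")))
  }
  if (any(sc > 1.5)) sc <- sc / 1000
  keep <- sc > min_score & n1 != n2
  g <- igraph::graph_from_data_frame(
    data.frame(from = n1[keep], to = n2[keep]),
    directed = FALSE,
    vertices = if (is.null(nodes)) NULL else
      data.frame(name = sort(unique(c(nodes, n1[keep], n2[keep]))))
  )
  igraph::simplify(g)
}

#' Compute the six node centralities of a PPI network
#'
#' For each node, computes the six topological centralities used for key
#' target screening:
#' \describe{
#'   \item{bc}{Raw (unnormalized) shortest-path betweenness over unordered
#'     node pairs excluding the node itself.}
#'   \item{cc}{Closeness per connected component:
#'     `(n_c - 1) / sum of distances` to the other members of the node's
#'     component of size `n_c`; isolated nodes score 0.}
#'   \item{dc}{Degree.}
#'   \item{ec}{Eigenvector centrality: the nonnegative unit-norm principal
#'     eigenvector of the largest connected component's adjacency matrix;
#'     nodes outside it score 0 (0 for all when the largest component has
#'     no edges).}
#'   \item{lac}{Local average connectivity: the mean degree of the node's
#'     neighbors within the subgraph induced by those neighbors; degree-0
#'     nodes score 0.}
#'   \item{nc}{Sum over incident edges of the edge clustering coefficient
#'     `triangles(v, w) / min(deg(v) - 1, deg(w) - 1)` (0 when the
#'     denominator is 0).}
#' }
#' Centralities are computed on the unweighted graph; edge confidence is a
#' filter, not a weight.
#'
#' @param g An `igraph` object, or a two-column edge data frame.
#' @return A `centrality_table`: tibble with columns `node`, `bc`, `cc`,
#'   `dc`, `ec`, `lac`, `nc`, one row per node.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' ppi_centralities(g)
#' @export
ppi_centralities <- function(g) {
  if (is.data.frame(g)) {
    g <- igraph::simplify(igraph::graph_from_data_frame(g[, 1:2],
                                                        directed = FALSE))
  }
  if (!igraph::is_igraph(g)) abort("`g` must be an igraph or edge table")
  n <- igraph::vcount(g)
  if (n == 0) abort("empty graph")
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))

  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(A)
  comp <- igraph::components(g)

  bc <- igraph::betweenness(g, directed = FALSE, weights = NULL)

  D <- igraph::distances(g)
  cc <- vapply(seq_len(n), function(v) {
    members <- which(comp$membership == comp$membership[v])
    if (length(members) <= 1) return(0)
    (length(members) - 1) / sum(D[v, members])
  }, numeric(1))

  ec <- rep(0, n)
  largest <- which.max(comp$csize)
  in_largest <- which(comp$membership == largest)
  if (length(in_largest) > 1 && sum(A[in_largest, in_largest]) > 0) {
    sub <- A[in_largest, in_largest, drop = FALSE]
    es <- eigen(sub, symmetric = TRUE)
    v1 <- es$vectors[, 1]
    if (sum(v1) < 0) v1 <- -v1
    ec[in_largest] <- pmax(v1, 0) / sqrt(sum(pmax(v1, 0)^2))
  }

  lac <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    sub <- A[nb, nb, drop = FALSE]
    mean(rowSums(sub))
  }, numeric(1))

  nc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) return(0)
    sum(vapply(nb, function(w) {
      denom <- min(deg[v] - 1, deg[w] - 1)
      if (denom <= 0) return(0)
      sum(A[v, ] * A[w, ]) / denom
    }, numeric(1)))
  }, numeric(1))

  structure(
    tibble(node = nodes, bc = unname(bc), cc = cc, dc = unname(deg),
           ec = ec, lac = lac, nc = nc),
    class = c("centrality_table", class(tibble()))
  )
}

#' Select key targets by the six-centrality median rule
#'
#' A node is a key target when, for every one of the six centralities, its
#' value is greater than or equal to that centrality's median over all
#' nodes. Medians interpolate the two middle order statistics for even
#' counts, so the rule is deterministic.
#'
#' @param centralities A [ppi_centralities()] table.
#' @return Sorted character vector of key-target node names.
#' @examples
#' g <- igraph::make_full_graph(4)
#' igraph::V(g)$name <- letters[1:4]
#' select_key_targets(ppi_centralities(g))
#' @export
select_key_targets <- function(centralities) {
  check_columns(centralities, c("node", "bc", "cc", "dc", "ec", "lac", "nc"),
                "centrality table")
  if (nrow(centralities) == 0) abort("centrality table is empty")
  metrics <- c("bc", "cc", "dc", "ec", "lac", "nc")
  meds <- vapply(centralities[metrics], median, numeric(1))
  keep <- rep(TRUE, nrow(centralities))
  for (m in metrics) keep <- keep & centralities[[m]] >= meds[[m]]
  sort(centralities$node[keep])
}
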