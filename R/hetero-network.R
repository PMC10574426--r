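.hetero_types <- c("compound", "target", "pathway", "function_BP",
                   "function_CC", "function_MF", "disease")

#' Build a heterogeneous compound-target-pathway-function network
#'
#' Unions one or more typed relation tables (compound–target,
#' disease–target, pathway–target, function–target, ...) into a single
#' undirected network, collapsing duplicate edges. Node types must come
#' from the fixed vocabulary `compound`, `target`, `pathway`,
#' `function_BP`, `function_CC`, `function_MF`, `disease`, and a node id
#' may carry only one type.
#'
#' @param relations A data frame with columns `from`, `from_type`, `to`,
#'   `to_type`, or a list of such data frames.
#' @return A `hetero_network`: list with `nodes` (tibble `id`, `type`) and
#'   `edges` (tibble `from`, `to`).
#' @examples
#' rel <- tibble::tibble(from = "quercetin", from_type = "compound",
#'                       to = "TNF", to_type = "target")
#' build_hetero_network(rel)
#' @export
build_hetero_network <- function(relations) {
  if (is.data.frame(relations)) relations <- list(relations)
  rel <- bind_rows(map(relations, as_tibble))
  if (nrow(rel) == 0) {
    return(structure(list(nodes = tibble(id = character(0),
                                         type = character(0)),
                          edges = tibble(from = character(0),
                                         to = character(0))),
                     class = "hetero_network"))
  }
  check_columns(rel, c("from", "from_type", "to", "to_type"),
                "relation table")
  bad_type <- setdiff(unique(c(rel$from_type, rel$to_type)), .hetero_types)
  if (length(bad_type) > 0) {
    abort(paste0("undeclared node type(s): ", paste(bad_type, collapse = ", "),
                 "; allowed: ", paste(.hetero_types, collapse = ", ")))
  }
  if (any(rel$from == rel$to)) abort("self-loop edge in relation table")
  nodes <- distinct(bind_rows(
    tibble(id = rel$from, type = rel$from_type),
    tibble(id = rel$to, type = rel$to_type)
  ))
  multi <- nodes$id[duplicated(nodes$id)]
  if (length(multi) > 0) {
    abort(paste0("node(s) declared with conflicting types: ",
                 paste(unique(multi), collapse = ", ")))
  }
  lo <- pmin(rel$from, rel$to); hi <- pmax(rel$from, rel$to)
  edges <- distinct(tibble(from = lo, to = hi))
  structure(list(nodes = arrange(nodes, .data$id), edges = arrange(edges, .data$from, .data$to)),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("Heterogeneous network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  print(table(x$nodes$type))
  invisible(x)
}

#' Rank nodes of one type by degree
#'
#' Degree is type-blind: every incident edge counts, whatever the type of
#' the node at the other end. The top `k` nodes of the requested type are
#' returned, sorted by descending degree with ties broken by ascending id
#' (deterministic); fewer than `k` existing nodes are all returned.
#'
#' @param net A [build_hetero_network()] result.
#' @param node_type One of the declared node types.
#' @param k Number of nodes to return (default 10, the usual core set size).
#' @return A `degree_ranking` tibble with `id`, `node_type`, `degree`.
#' @export
rank_by_degree <- function(net, node_type, k = 10) {
  if (!inherits(net, "hetero_network")) abort("`net` must be a hetero_network")
  if (!node_type %in% .hetero_types) {
    abort(paste0("unknown node type '", node_type, "'"))
  }
  if (k < 1) abort("`k` must be at least 1")
  counts <- table(c(net$edges$from, net$edges$to))
  nodes <- net$nodes |> filter(.data$type == node_type)
  out <- tibble(id = nodes$id, node_type = node_type,
                degree = as.integer(counts[nodes$id])) |>
    mutate(degree = ifelse(is.na(.data$degree), 0L, .data$degree)) |>
    arrange(desc(.data$degree), .data$id) |>
    slice_head(n = min(k, nrow(nodes)))
  structure(out, class = c("degree_ranking", class(tibble())))
}

#' Export a heterogeneous network as a SIF-style edge table
#'
#' @param net A [build_hetero_network()] result.
#' @param path File to write (tab-separated `from`, `interaction`, `to`,
#'   where `interaction` is `fromtype-totype`).
#' @return The written tibble, invisibly.
#' @export
write_sif <- function(net, path) {
  type_of <- setNames(net$nodes$type, net$nodes$id)
  out <- tibble(from = net$edges$from,
                interaction = paste0(type_of[net$edges$from], "-",
                                     type_of[net$edges$to]),
                to = net$edges$to)
  readr::write_tsv(out, path)
  invisible(out)
}
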