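#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more study genes in a term:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, where `N` is the
#' background size, `K` the term size within the background and `n` the
#' study size within the background. Evaluated through the stable
#' log-space tail routine of [stats::phyper()].
#'
#' @param N,K,n,k Integer scalars or vectors (recycled).
#' @return `P(X >= k)`, in `[0, 1]`.
#' @examples
#' hypergeom_upper(10, 4, 3, 2)  # 1/3
#' @export
hypergeom_upper <- function(N, K, n, k) {
  args <- cbind(N = N, K = K, n = n, k = k)
  if (any(is.na(args)) || any(args < 0) || any(args[, "K"] > args[, "N"]) ||
      any(args[, "n"] > args[, "N"]) ||
      any(args[, "k"] > pmin(args[, "K"], args[, "n"]))) {
    abort("infeasible hypergeometric arguments: need 0 <= k <= min(K, n), K,n <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `p_adj(i) = min over j >= i of m * p(j) / j` on the sorted p-values,
#' capped at 1 and returned in input order (delegated to
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Over-representation analysis against a gene-set collection
#'
#' Tests each term with at least one study gene by the upper-tail
#' hypergeometric statistic, adjusts p-values by Benjamini-Hochberg within
#' each category separately (KEGG, BP, CC, MF — enrichment of pathways and
#' of the three ontology branches is reported separately), keeps results
#' with `p_adjust < alpha` (strict), sorts by ascending `p_adjust`, then
#' descending `count`, then `term_id`, and truncates to `top_k` terms per
#' category.
#'
#' The background universe defaults to all genes appearing in the
#' collection. `gene_ratio` is `count / n_study` where `n_study` is the
#' number of study genes in the background, kept alongside so the ratio is
#' exact rational bookkeeping.
#'
#' @param study Character vector or [target_set()] of study genes.
#' @param collection Gene-set collection: tibble with `term_id`,
#'   `term_name`, `category`, `genes` (list-column), e.g. from
#'   [sim_annotations()] or [read_gmt()].
#' @param background Optional explicit background universe; defaults to the
#'   union of all term members.
#' @param alpha Strict adjusted-p cutoff (default 0.05); `alpha = 1` with
#'   `top_k = Inf` returns every overlapping term.
#' @param top_k Terms kept per category after sorting (default `Inf`).
#' @return A `herb_ora` tibble with columns `term_id`, `term_name`,
#'   `category`, `count`, `n_study`, `gene_ratio`, `p_value`, `p_adjust`,
#'   `genes` (hit genes, list-column).
#' @examples
#' bg <- sprintf("G%02d", 1:50)
#' coll <- tibble::tibble(term_id = "t1", term_name = "t1",
#'                        category = "KEGG", genes = list(bg[1:10]))
#' run_ora(bg[1:10], coll, background = bg, alpha = 1)
#' @export
run_ora <- function(study, collection, background = NULL, alpha = 0.05,
                    top_k = Inf) {
  check_columns(collection, c("term_id", "term_name", "category", "genes"),
                "gene-set collection")
  study <- set_members(study)
  background <- if (is.null(background)) {
    sort(unique(normalize_gene(unlist(collection$genes))))
  } else {
    sort(unique(set_members(background)))
  }
  N <- length(background)
  study_bg <- intersect(study, background)
  n_study <- length(study_bg)
  if (n_study == 0) abort("no study gene lies in the background universe")

  rows <- purrr::pmap(
    list(collection$term_id, collection$term_name, collection$category,
         collection$genes),
    function(id, nm, cat, members) {
      members <- intersect(normalize_gene(members), background)
      hits <- intersect(members, study_bg)
      k <- length(hits)
      if (k == 0) return(NULL)
      tibble(term_id = id, term_name = nm, category = cat, count = k,
             n_study = n_study, gene_ratio = k / n_study,
             p_value = hypergeom_upper(N, length(members), n_study, k),
             genes = list(sort(hits)))
    })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    res <- tibble(term_id = character(0), term_name = character(0),
                  category = character(0), count = integer(0),
                  n_study = integer(0), gene_ratio = numeric(0),
                  p_value = numeric(0), p_adjust = numeric(0),
                  genes = list())
  } else {
    res <- res |>
      group_by(.data$category) |>
      mutate(p_adjust = bh_adjust(.data$p_value)) |>
      ungroup() |>
      filter(.data$p_adjust < alpha) |>
      arrange(.data$p_adjust, desc(.data$count), .data$term_id) |>
      group_by(.data$category) |>
      slice_head(n = if (is.finite(top_k)) top_k else .Machine$integer.max) |>
      ungroup() |>
      select("term_id", "term_name", "category", "count", "n_study",
             "gene_ratio", "p_value", "p_adjust", "genes")
  }
  structure(res, class = c("herb_ora", class(tibble())),
            background_size = N, study_size = n_study, alpha = alpha,
            adjust_method = "BH, per category")
}

#' @rdname run_ora
#' @param x A `herb_ora` result.
#' @param ... Unused.
#' @export
glance.herb_ora <- function(x, ...) {
  tibble(n_terms = nrow(x), n_categories = length(unique(x$category)),
         background_size = attr(x, "background_size"),
         study_size = attr(x, "study_size"), alpha = attr(x, "alpha"),
         adjust_method = attr(x, "adjust_method"))
}
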